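test_that("one-way fixed ANOVA reproduces the closed-form F and the squared t", {
  sheet <- oneway_sheet(3)
  fit <- fit_gene_anova(c(1, 2, 3, 4, 5, 6), sheet, model_spec("grp"))
  row <- fit$table
  expect_equal(row$statistic, 13.5)
  expect_equal(row$p.value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(row$p.value, 0.0213, tolerance = 1e-2)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(row$statistic, unname(tt$statistic)^2)
})

test_that("constant response degenerates to zero components, 100% residual", {
  sheet <- paired_sheet(4)
  fit <- fit_gene_anova(rep(7, nrow(sheet)), sheet, spec_combined())
  expect_true(all(fit$table$sumsq < 1e-20))
  expect_true(all(fit$components$estimate == 0))
  pv <- fit$pct_var
  expect_equal(pv$pct[pv$term == "residual"], 100)
  expect_true(all(pv$pct[pv$term != "residual"] == 0))
})

test_that("sequential SS matches the aov() decomposition for all-fixed models", {
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 12
    sheet <- tibble::tibble(
      sample = paste0("s", 1:n),
      f1 = factor(sample(c("a", "b"), n, replace = TRUE)),
      f2 = factor(sample(c("x", "y", "z"), n, replace = TRUE))
    )
    # guard against degenerate draws
    if (nlevels(droplevels(sheet$f1)) < 2 ||
      nlevels(droplevels(sheet$f2)) < 3) next
    y <- rnorm(n)
    fit <- fit_gene_anova(y, sheet, model_spec(c("f1", "f2")))
    oracle <- anova(stats::lm(y ~ f1 + f2, data = sheet))
    expect_equal(fit$table$sumsq, oracle$`Sum Sq`[1:2], tolerance = 1e-10)
    expect_equal(fit$table$statistic, oracle$`F value`[1:2], tolerance = 1e-10)
    expect_equal(fit$table$p.value, oracle$`Pr(>F)`[1:2], tolerance = 1e-10)
    expect_equal(fit$residual$sumsq, oracle$`Sum Sq`[3], tolerance = 1e-10)
  }
})

test_that("MoM variance components equal the balanced closed form to 1e-8", {
  set.seed(11)
  n_grp <- 12
  reps <- 4
  g <- factor(rep(seq_len(n_grp), each = reps))
  y <- rnorm(n_grp, 0, 1.3)[g] + rnorm(n_grp * reps, 0, 0.8)
  sheet <- tibble::tibble(sample = paste0("s", seq_along(y)), subj = g)
  fit <- fit_gene_anova(y, sheet, model_spec("subj", random = "subj"))
  ms_b <- fit$table$meansq[1]
  ms_w <- fit$residual$meansq
  comp <- fit$components
  expect_equal(comp$estimate[comp$component == "subj"],
    max((ms_b - ms_w) / reps, 0), tolerance = 1e-8)
  expect_equal(comp$estimate[comp$component == "residual"], ms_w,
    tolerance = 1e-8)
})

test_that("MoM recovers planted variance components on average", {
  ests <- t(vapply(1:30, function(s) {
    set.seed(400 + s)
    n_grp <- 50
    reps <- 4
    g <- factor(rep(seq_len(n_grp), each = reps))
    y <- rnorm(n_grp, 0, 1)[g] + rnorm(n_grp * reps, 0, 1)
    sheet <- tibble::tibble(sample = paste0("s", seq_along(y)), subj = g)
    fit <- fit_gene_anova(y, sheet, model_spec("subj", random = "subj"))
    setNames(fit$components$estimate, fit$components$component)
  }, c(subj = 0, residual = 0)))
  expect_lt(abs(mean(ests[, "subj"]) - 1), 0.15)
  expect_lt(abs(mean(ests[, "residual"]) - 1), 0.1)
})

test_that("combined-model case component uses its EMS denominator on balanced designs", {
  # balanced paired design: E[MS_case] = sigma_e^2 + 4 sigma_case^2
  set.seed(12)
  sheet <- paired_sheet(10)
  y <- rnorm(10, 0, 1)[as.integer(sheet$case)] + rnorm(nrow(sheet), 0, 0.7)
  fit <- fit_gene_anova(y, sheet, spec_combined())
  ms <- fit$table
  ms_case <- ms$meansq[ms$term == "case"]
  ms_res <- fit$residual$meansq
  comp <- fit$components
  expect_equal(comp$estimate[comp$component == "case"],
    max((ms_case - ms_res) / 4, 0), tolerance = 1e-8)
  # fixed-term denominators collapse to the residual MS on this design
  f_tissue <- ms$statistic[ms$term == "tissue"]
  expect_equal(f_tissue, ms$meansq[ms$term == "tissue"] / ms_res,
    tolerance = 1e-10)
  expect_equal(ms$df_denom[ms$term == "tissue"], fit$residual$df[1],
    tolerance = 1e-6)
})

test_that("null-simulation p-values are approximately uniform for every term", {
  set.seed(13)
  sheet <- paired_sheet(8)
  mat <- matrix(rnorm(100 * nrow(sheet)), 100,
    dimnames = list(sprintf("g%03d", 1:100), sheet$sample))
  fit <- genomewide_anova(mat, sheet, spec_combined())
  for (tm in c("tissue", "storage", "tissue:storage")) {
    p <- fit$table$p.value[fit$table$term == tm]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("genomewide table is consistent with single-gene fits and label-invariant", {
  set.seed(14)
  sheet <- paired_sheet(5)
  mat <- matrix(rnorm(3 * nrow(sheet)), 3,
    dimnames = list(c("gA", "gB", "gC"), sheet$sample))
  fit <- genomewide_anova(mat, sheet, spec_combined())
  one <- fit_gene_anova(mat["gB", ], sheet, spec_combined(), gene = "gB")
  expect_equal(
    dplyr::filter(fit$table, gene == "gB")$statistic,
    one$table$statistic, tolerance = 1e-12
  )
  # permuting samples together with the sheet leaves results unchanged
  perm <- sample(nrow(sheet))
  fit2 <- genomewide_anova(mat[, perm], sheet[perm, ], spec_combined())
  expect_equal(fit$table$statistic, fit2$table$statistic, tolerance = 1e-10)
  expect_equal(fit$table$p.value, fit2$table$p.value, tolerance = 1e-10)
})

test_that("unbalanced designs (dropped sample) keep EMS equating coherent", {
  set.seed(15)
  sheet <- paired_sheet(8)[-3, ] # one excluded sample
  y <- rnorm(8, 0, 1)[as.integer(sheet$case)] + rnorm(nrow(sheet), 0, 0.5)
  fit <- fit_gene_anova(y, sheet, spec_combined())
  expect_true(all(is.finite(fit$table$statistic)))
  comp <- fit$components
  expect_true(all(comp$estimate >= 0))
  # percent variance still sums to 100
  expect_equal(sum(fit$pct_var$pct), 100, tolerance = 1e-8)
})

test_that("block-age covariate consumes one df and its slope is detected", {
  set.seed(16)
  sim <- simulate_dataset(sim_params(
    n_genes = 60, n_patients = 12, seed = 16,
    frac_tissue_de = 0, frac_storage_de = 0, frac_interaction = 0,
    frac_coordinated_sets = 0, block_age_slope = 1.5, batch_sd = 0.1
  ))
  idx <- sim$sheet$storage == "FFPE"
  sheet <- droplevels(sim$sheet[idx, ])
  fit <- genomewide_anova(sim$expr[, idx], sheet, spec_within_storage())
  tb <- fit$table
  expect_true(all(tb$df[tb$term == "block_age"] == 1))
  # a strong common slope makes block_age the dominant small-p term
  p_age <- tb$p.value[tb$term == "block_age"]
  expect_gt(mean(p_age < 0.05, na.rm = TRUE), 0.5)
})

test_that("model_spec validation catches malformed declarations", {
  expect_error(model_spec(character(0)), "at least one")
  expect_error(model_spec("a", random = "b"), "random terms")
  expect_error(model_spec(c("a", "a:b")), "reference declared")
  expect_error(model_spec("a", covariates = "b"), "covariates")
  expect_error(
    model_spec(c("a", "b"), random = "a", covariates = "a"),
    "both random"
  )
})
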