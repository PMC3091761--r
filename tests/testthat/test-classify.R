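test_that("all three classifiers reach 100% on a separable fixture", {
  fx <- separable_fixture(n_per_class = 20, seed = 51)
  for (cl in c("knn1", "nearest_centroid", "lda")) {
    r <- cross_validate(fx$mat, fx$sheet, "storage",
      cv_spec(cl, outer_folds = 5, inner_folds = 3,
        feature_counts = c(5, Inf), seed = 3))
    expect_equal(r$accuracy_pct, 100)
    expect_equal(r$n_correct, r$n_total)
  }
})

test_that("pure-noise features give chance-level accuracy", {
  accs <- vapply(1:25, function(s) {
    fx <- null_fixture(n_per_class = 12, n_genes = 40, seed = 1100 + s)
    r <- cross_validate(fx$mat, fx$sheet, "storage",
      cv_spec("knn1", outer_folds = 4, inner_folds = 3,
        feature_counts = Inf, nested = FALSE, seed = s))
    r$accuracy_pct
  }, 0)
  mc_se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * mc_se + 2)
})

test_that("LDA approaches the analytic Bayes rate on a 1-D Gaussian problem", {
  set.seed(52)
  n <- 1500
  lab <- rep(c("FF", "FFPE"), each = n / 2)
  x <- rnorm(n, ifelse(lab == "FFPE", 1, -1), 1)
  mat <- matrix(x, 1, dimnames = list("g1", paste0("s", 1:n)))
  sheet <- tibble::tibble(sample = colnames(mat), storage = factor(lab))
  r <- cross_validate(mat, sheet, "storage",
    cv_spec("lda", outer_folds = 5, inner_folds = 3,
      feature_counts = Inf, nested = FALSE, seed = 4))
  bayes <- 100 * pnorm(1)
  expect_lt(abs(r$accuracy_pct - bayes), 2.5)
})

test_that("nested CV with in-fold selection shows no selection-bias leakage", {
  # high-dimensional noise with random labels: a leaky pipeline (selection on
  # the full data) inflates accuracy well above chance; the fold-local
  # pipeline must not
  leaky <- honest <- numeric(8)
  for (s in seq_len(8)) {
    set.seed(1200 + s)
    n <- 24
    mat <- matrix(rnorm(500 * n), 500,
      dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:n)))
    lab <- sample(rep(c("FF", "FFPE"), each = n / 2))
    sheet <- tibble::tibble(
      sample = colnames(mat), storage = factor(lab),
      tissue = factor(rep(c("normal", "tumor"), n / 2)),
      case = factor(rep(seq_len(n / 2), each = 2))
    )
    r <- cross_validate(mat, sheet, "storage",
      cv_spec("nearest_centroid", outer_folds = 4, inner_folds = 3,
        feature_counts = 10,
        select_spec = model_spec(c("tissue", "storage")), seed = s))
    honest[s] <- r$accuracy_pct
    # deliberate leakage computed here in the test: rank genes on ALL data
    d <- abs(rowMeans(mat[, lab == "FF"]) - rowMeans(mat[, lab == "FFPE"]))
    top <- names(sort(d, decreasing = TRUE))[1:10]
    r_leak <- cross_validate(mat[top, ], sheet, "storage",
      cv_spec("nearest_centroid", outer_folds = 4, inner_folds = 3,
        feature_counts = Inf, nested = FALSE, seed = s))
    leaky[s] <- r_leak$accuracy_pct
  }
  expect_gt(mean(leaky), mean(honest) + 10) # the bias is real...
  expect_lt(abs(mean(honest) - 50), 12) # ...and the guarded CV avoids it
})

test_that("feature selection is fold-local and guards against test-id leakage", {
  fx <- separable_fixture(n_per_class = 10, seed = 53)
  expect_error(
    select_features_for_cv(
      fx$mat, fx$sheet, "storage", 5,
      test_ids = fx$sheet$sample[1]
    ),
    "leakage"
  )
  expect_error(
    select_features_for_cv(fx$mat, fx$sheet, "storage", 10000),
    "exceeds"
  )
  # k = n_genes is the identity selection
  all_feats <- select_features_for_cv(fx$mat, fx$sheet, "storage", Inf)
  expect_setequal(all_feats, rownames(fx$mat))
})

test_that("a planted storage-effect gene is ranked first", {
  hits <- vapply(1:15, function(s) {
    set.seed(1300 + s)
    sheet <- paired_sheet(8)
    n <- nrow(sheet)
    mat <- matrix(rnorm(80 * n, 0, 0.5), 80,
      dimnames = list(sprintf("g%02d", 1:80), sheet$sample))
    mat[40, sheet$storage == "FFPE"] <- mat[40, sheet$storage == "FFPE"] + 2
    top <- select_features_for_cv(mat, sheet, "storage", 1)
    top == "g40"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("knn1 distance ties resolve to the smallest training index", {
  train <- matrix(c(0, 0, 1), ncol = 1) # samples 1 and 2 equidistant from 0
  labs <- c("A", "B", "B")
  pred <- ffpeconcord:::knn1_predict(train, labs, matrix(0, 1, 1))
  expect_equal(pred, "A")
  # knn1 with self-inclusion classifies the training set perfectly
  fx <- separable_fixture(5, seed = 54)
  x <- t(fx$mat)
  pred_self <- ffpeconcord:::knn1_predict(x, as.character(fx$sheet$storage), x)
  expect_equal(pred_self, as.character(fx$sheet$storage))
})

test_that("signature prediction reports counts, drops absent ids, and tracks separability", {
  fx <- separable_fixture(n_per_class = 15, seed = 55)
  lab <- fx$sheet$storage
  # signature = the truly separating genes: perfect accuracy
  res <- signature_predict(fx$mat, lab, c(paste0("g", 1:5), "missing_id"),
    seed = 5)
  expect_equal(res$accuracy_pct, 100)
  expect_equal(res$n_dropped, 1)
  expect_equal(res$n_correct, res$n_total)
  # pure-noise signature: near chance
  accs <- vapply(1:10, function(s) {
    fx0 <- null_fixture(n_per_class = 12, seed = 1400 + s)
    signature_predict(fx0$mat, fx0$sheet$storage, paste0("g", 10:20),
      seed = s)$accuracy_pct
  }, 0)
  expect_lt(abs(mean(accs) - 50), 12)
  expect_error(signature_predict(fx$mat, lab, "nope"), "no signature gene")
})

test_that("replicate_r2 matches hand-computed cases and the null property", {
  x <- c(0, 1, 2)
  expect_equal(replicate_r2(x, x)$r_squared, 1)
  expect_equal(replicate_r2(x, x)$n_beyond_boundary, 0)
  # (0,0), (1,2), (2,4): r2 = 1; only |2-4| = 2 strictly exceeds log2(2) = 1
  r <- replicate_r2(c(0, 1, 2), c(0, 2, 4))
  expect_equal(r$r_squared, 1)
  expect_equal(r$n_beyond_boundary, 1)
  set.seed(56)
  big <- replicate_r2(rnorm(1e4), rnorm(1e4))
  expect_lt(big$r_squared, 0.01)
  expect_error(replicate_r2(1:3, rep(1, 3)), "zero-variance")
  expect_error(replicate_r2(1:3, 1:4), "equal length")
})

test_that("gene-list Venn overlaps reproduce constructed shared counts", {
  shared <- paste0("s", 1:315)
  ff <- c(shared, paste0("f", 1:(1275 - 315)))
  ffpe <- c(shared, paste0("p", 1:(966 - 315)))
  ov <- list_overlap(list(FF = ff, FFPE = ffpe))
  expect_equal(ov$pairs$shared, 315)
  expect_equal(ov$pairs$n_a, 1275)
  expect_equal(ov$pairs$n_b, 966)
  # disjoint and identical edge cases
  expect_equal(list_overlap(list(a = "x", b = "y"))$pairs$shared, 0)
  same <- list_overlap(list(a = ff, b = ff))$pairs
  expect_equal(same$shared, 1275)
  expect_equal(same$pct_of_a, 100)
})

test_that("standardized effect size follows log2(FC)/sigma", {
  expect_equal(standardized_effect_size(2, 0.5), 2)
  expect_equal(standardized_effect_size(1, 0.7), 0)
  expect_equal(standardized_effect_size(1.4, 0.5), 0.97085, tolerance = 1e-4)
  expect_error(standardized_effect_size(-1, 0.5), "positive")
  expect_error(standardized_effect_size(2, 0), "positive")
})
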