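test_that("GO-enrichment chi-square equals the textbook 2x2 formula", {
  u <- sprintf("g%05d", 1:10000)
  gl <- u[1:100]
  sets <- gene_set_collection(list(S = c(u[1:10], u[101:190])))
  e <- suppressWarnings(go_enrichment(gl, u, sets))
  # textbook N (ad - bc)^2 / (row and column margins) on the same 2x2
  tab <- matrix(c(10, 90, 100, 9900), 2, byrow = TRUE)
  n <- sum(tab)
  chi_hand <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(e$chisq, chi_hand, tolerance = 1e-10)
  expect_equal(e$chisq, 74.44717, tolerance = 1e-5)
  expect_equal(e$p.value, pchisq(chi_hand, 1, lower.tail = FALSE),
    tolerance = 1e-12)
  expect_equal(e$score, -log(e$p.value), tolerance = 1e-10)
})

test_that("enrichment score conventions: no enrichment, p = 1, log bases", {
  u <- paste0("g", 1:1000)
  # list proportion equals chip proportion: chi-square 0, score 0
  sets <- gene_set_collection(list(S = u[1:100])) # 10% of chip
  gl <- c(u[1:10], u[101:190]) # 10% of the 100-gene list in S
  e <- suppressWarnings(go_enrichment(gl, u, sets))
  expect_equal(e$chisq, 0)
  expect_equal(e$p.value, 1)
  expect_equal(e$score, 0)
  # log10 convention
  sets2 <- gene_set_collection(list(S = u[1:50]))
  gl2 <- u[1:40]
  e_nat <- suppressWarnings(go_enrichment(gl2, u, sets2))
  e_10 <- suppressWarnings(go_enrichment(gl2, u, sets2, log_base = "10"))
  expect_equal(e_10$score, e_nat$score / log(10), tolerance = 1e-10)
  # empty list warns and scores 0
  expect_warning(e0 <- go_enrichment(character(0), u, sets), "empty")
  expect_equal(e0$score, 0)
  expect_error(go_enrichment("not_on_chip", u, sets), "subset")
})

test_that("running-sum ES equals the brute-force scan on exhaustive small lists", {
  set.seed(41)
  n_cases <- 0
  for (n in 5:12) {
    metric <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    sizes <- unique(c(1, 2, 3, n - 1))
    for (k in sizes[sizes < n]) {
      for (idx in utils::combn(n, k, simplify = FALSE)) {
        in_set <- seq_len(n) %in% idx
        expect_equal(
          es_via_package(metric, in_set, 1),
          es_brute_force(metric, in_set, 1),
          tolerance = 1e-12
        )
        expect_equal(
          es_via_package(metric, in_set, 0),
          es_brute_force(metric, in_set, 0),
          tolerance = 1e-12
        )
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gt(n_cases, 400)
})

test_that("extremal and hand-worked ES configurations", {
  # set occupying exactly the top |S| ranks reaches the maximal ES of 1
  metric <- 10:1
  expect_equal(es_via_package(metric, c(TRUE, TRUE, rep(FALSE, 8)), 1), 1)
  # unweighted 2-gene set at positions 1 and 10: run peaks at +1/2 after the
  # first hit (and dips to -1/2 before the last)
  expect_equal(es_via_package(metric, c(TRUE, rep(FALSE, 8), TRUE), 0), 0.5)
  # |ES| never exceeds 1
  set.seed(42)
  for (i in 1:20) {
    s <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    if (all(s) || !any(s)) next
    expect_lte(abs(es_via_package(metric, s, 1)), 1)
  }
})

test_that("gsea detects a planted top-ranked set and respects invariances", {
  set.seed(43)
  mat <- matrix(rnorm(60 * 12), 60,
    dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:12)))
  labs <- rep(c("A", "B"), each = 6)
  mat[1:10, labs == "B"] <- mat[1:10, labs == "B"] + 3
  sets <- gene_set_collection(list(
    hot = sprintf("g%02d", 1:10),
    cold = sprintf("g%02d", 31:50)
  ))
  r <- gsea(mat, labs, sets, n_permutations = 200, seed = 1, min_size = 5)
  hot <- r[r$set == "hot", ]
  expect_gt(hot$es, 0.8)
  expect_lt(hot$p.value, 0.05)
  expect_equal(unname(sign(hot$nes)), unname(sign(hot$es)))
  expect_true(all(abs(r$es) <= 1))
  expect_true(all(r$p.value >= 0 & r$p.value <= 1, na.rm = TRUE))
  # adding a gene-wise constant to both classes leaves ES unchanged (exact)
  mat2 <- mat + rnorm(60)[row(mat)]
  r2 <- gsea(mat2, labs, sets, n_permutations = 200, seed = 1, min_size = 5)
  expect_equal(r$es, r2$es, tolerance = 1e-12)
  # determinism under the same seed
  r3 <- gsea(mat, labs, sets, n_permutations = 200, seed = 1, min_size = 5)
  expect_identical(r$nes, r3$nes)
})

test_that("gsea input contracts: classes, permutations, size window, degenerate genes", {
  set.seed(44)
  mat <- matrix(rnorm(40 * 12), 40,
    dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
  labs <- rep(c("A", "B"), each = 6)
  sets <- gene_set_collection(list(S = paste0("g", 1:20)))
  expect_error(gsea(mat, rep("A", 12), sets), "two classes")
  expect_error(gsea(mat[, 1:7], c(rep("A", 5), "B", "B"), sets), "at least 3")
  expect_error(gsea(mat, labs, sets, n_permutations = 5), "10 permutations")
  expect_error(gsea(mat, labs, sets, min_size = 30), "no gene set")
  mat[3, ] <- 5 # zero-variance gene dropped with count
  r <- gsea(mat, labs, sets, n_permutations = 50, seed = 2, min_size = 5)
  expect_equal(attr(r, "n_degenerate"), 1L)
})

test_that("gsea null calibration: about 5% of sets reach p < 0.05", {
  fracs <- vapply(1:4, function(s) {
    set.seed(900 + s)
    mat <- matrix(rnorm(150 * 12), 150,
      dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:12)))
    labs <- sample(rep(c("A", "B"), each = 6))
    sets <- gene_set_collection(setNames(
      lapply(1:15, function(i) sample(rownames(mat), 15)),
      paste0("S", 1:15)
    ))
    r <- gsea(mat, labs, sets, n_permutations = 200, seed = s, min_size = 5)
    mean(r$p.value < 0.05, na.rm = TRUE)
  }, 0)
  # 60 set-tests in total: expect a small positive rate near nominal
  expect_lt(mean(fracs), 0.15)
})

test_that("go_anova single-gene set reproduces the per-gene paired tissue F", {
  sim <- simulate_dataset(sim_params(n_genes = 40, n_patients = 8, seed = 45,
    n_gene_sets = 2, set_size_range = c(3, 5)))
  idx <- sim$sheet$storage == "FF"
  g <- rownames(sim$expr)[7]
  rec <- go_anova(sim$expr[, idx], sim$sheet[idx, ], g)
  ref <- fit_gene_anova(
    sim$expr[g, idx], droplevels(sim$sheet[idx, ]),
    model_spec(c("tissue", "case"), random = "case")
  )
  expect_equal(rec$anova$statistic[1], ref$table$statistic[1],
    tolerance = 1e-10)
  expect_equal(rec$anova$p.value[1], ref$table$p.value[1], tolerance = 1e-10)
})

test_that("go_anova: identical member genes give zero gene-to-gene SS", {
  sim <- simulate_dataset(sim_params(n_genes = 20, n_patients = 6, seed = 46,
    n_gene_sets = 2, set_size_range = c(3, 5)))
  idx <- sim$sheet$storage == "FF"
  mat <- sim$expr[, idx]
  mat["g00002", ] <- mat["g00001", ]
  rec <- go_anova(mat, sim$sheet[idx, ], c("g00001", "g00002"))
  expect_equal(rec$anova$sumsq[rec$anova$term == "gene"], 0, tolerance = 1e-10)
})

test_that("go_anova null calibration and power for a common tissue shift", {
  null_p <- shift_p <- numeric(12)
  for (s in seq_len(12)) {
    sim <- simulate_dataset(sim_params(
      n_genes = 60, n_patients = 10, seed = 1000 + s,
      n_gene_sets = 2, set_size_range = c(3, 5),
      frac_tissue_de = 0, frac_storage_de = 0, frac_interaction = 0,
      frac_coordinated_sets = 0
    ))
    idx <- sim$sheet$storage == "FF"
    members <- rownames(sim$expr)[1:15]
    rec0 <- go_anova(sim$expr[, idx], sim$sheet[idx, ], members)
    null_p[s] <- rec0$anova$p.value[1]
    m2 <- sim$expr
    tum <- idx & sim$sheet$tissue == "tumor"
    m2[members, tum] <- m2[members, tum] + 1
    rec1 <- go_anova(m2[, idx], sim$sheet[idx, ], members)
    shift_p[s] <- rec1$anova$p.value[1]
  }
  # null p roughly uniform: not systematically small
  expect_gt(mean(null_p > 0.05), 0.6)
  # a 1 log2-unit shared shift is detected at p < 0.01 essentially always
  expect_gte(mean(shift_p < 0.01), 0.9)
})

test_that("setlist overlaps reproduce two-decimal shares on known list sizes", {
  mk <- function(n, prefix) paste0(prefix, seq_len(n))
  shared <- paste0("c", 1:38)
  gsea_ff <- c(shared, mk(62, "f"))
  gsea_ffpe <- c(shared, mk(402, "p"))
  ov <- setlist_overlap(list(ff = gsea_ff, ffpe = gsea_ffpe))
  expect_equal(ov$pairs$shared, 38)
  expect_equal(ov$pairs$pct_of_a, 38.00)
  expect_equal(ov$pairs$pct_of_b, 8.64)

  shared2 <- paste0("c", 1:641)
  a <- c(shared2, mk(883 - 641, "a"))
  b <- c(shared2, mk(1034 - 641, "b"))
  ov2 <- setlist_overlap(list(ff = a, ffpe = b))
  expect_equal(ov2$pairs$pct_of_a, 72.59)
  expect_equal(ov2$pairs$pct_of_b, 61.99)

  # identical lists overlap 100%, Venn regions partition the union
  ov3 <- setlist_overlap(list(x = a, y = a, z = b))
  prs <- ov3$pairs
  expect_equal(prs$pct_of_a[prs$list_a == "x" & prs$list_b == "y"], 100)
  expect_equal(sum(ov3$regions$count), length(union(a, b)))
  expect_error(setlist_overlap(list(a = a)), "at least two")
})

test_that("running-sum ES agrees with an independent GSEA implementation", {
  set.seed(47)
  for (i in 1:10) {
    n <- 60
    stats <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    idx <- sort(sample(n, sample(5:15, 1)))
    mine <- es_via_package(stats, seq_len(n) %in% idx, 1)
    ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})
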