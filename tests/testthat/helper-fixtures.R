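# Small fixture builders shared across the test files. Everything is built
# in code; no stored data.

# minimal paired tumor/normal x FF/FFPE sheet without simulating expression
paired_sheet <- function(n_patients) {
  sheet <- tidyr::expand_grid(
    case = factor(sprintf("p%02d", seq_len(n_patients))),
    tissue = factor(c("normal", "tumor"), levels = c("normal", "tumor")),
    storage = factor(c("FF", "FFPE"), levels = c("FF", "FFPE"))
  )
  sheet$sample <- paste(sheet$case, sheet$tissue, sheet$storage, sep = "_")
  sheet
}

# two-group one-way layout
oneway_sheet <- function(n_per_group, levels = c("a", "b")) {
  tibble::tibble(
    sample = paste0("s", seq_len(n_per_group * length(levels))),
    grp = factor(rep(levels, each = n_per_group), levels = levels)
  )
}

# brute-force GSEA enrichment score: per-position scan of the running sum
es_brute_force <- function(metric_sorted, in_set, weight_p) {
  n <- length(metric_sorted)
  nh <- sum(in_set)
  w <- abs(metric_sorted)^weight_p
  nr <- sum(w[in_set])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (in_set[i]) {
      if (nr > 0) w[i] / nr else 1 / nh
    } else {
      -1 / (n - nh)
    }
    if (abs(run) > abs(best) + 1e-9) best <- run
  }
  best
}

# internal running-sum ES, reached through the exported gsea() machinery
es_via_package <- function(metric_sorted, in_set, weight_p) {
  ffpeconcord:::running_es(metric_sorted, in_set, weight_p)
}

# separable two-class expression fixture for classifier tests
separable_fixture <- function(n_per_class = 20, n_genes = 30, shift = 10,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  mat <- matrix(rnorm(n_genes * n), n_genes,
    dimnames = list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n))))
  lab <- rep(c("FF", "FFPE"), each = n_per_class)
  mat[1:5, lab == "FFPE"] <- mat[1:5, lab == "FFPE"] + shift
  sheet <- tibble::tibble(
    sample = colnames(mat),
    storage = factor(lab),
    tissue = factor(rep(c("normal", "tumor"), n / 2)),
    case = factor(rep(seq_len(n / 2), each = 2))
  )
  list(mat = mat, sheet = sheet)
}

null_fixture <- function(n_per_class = 20, n_genes = 30, seed = 1) {
  fx <- separable_fixture(n_per_class, n_genes, shift = 0, seed = seed)
  fx
}
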