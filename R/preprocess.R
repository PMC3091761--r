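#' Detection calls against negative-control probes
#'
#' A gene is "detected" in a sample when its signal is significantly higher
#' than the negative-control background on the same sample. With probe-level
#' replicates available, a one-sided Welch two-sample t-test of the gene's
#' probe values against the sample's negative controls is used; with only
#' gene-level values, a one-sided z-score against the controls' mean/SD.
#'
#' @param expr Genes x samples matrix (gene-level, e.g. probe means). Used
#'   when `probes` is `NULL`.
#' @param controls Negative-control intensities, a matrix (controls x samples,
#'   same sample order/names as `expr`) on the same scale as the expression
#'   values.
#' @param alpha Detection significance level, in (0, 1).
#' @param probes Optional probe-level matrix (probes x samples).
#' @param probe_map Character vector mapping rows of `probes` to gene ids
#'   (required with `probes`).
#' @return A list of class `detection_result`: `p` (genes x samples detection
#'   p-value matrix), `detected` (logical matrix at `alpha`), `counts` (tibble
#'   with per-sample detected-gene counts and shares), `alpha`.
#' @export
detection_calls <- function(expr, controls, alpha = 0.05,
                            probes = NULL, probe_map = NULL) {
  if (alpha <= 0 || alpha >= 1) fc_abort("alpha must be in (0, 1)")
  if (is.null(controls)) fc_abort("negative-control intensities are required")
  controls <- as.matrix(controls)
  if (nrow(controls) < 20) {
    fc_abort("need at least 20 negative controls per sample")
  }
  ctrl_mean <- colMeans(controls)
  ctrl_var <- apply(controls, 2, var)
  n_ctrl <- nrow(controls)

  if (!is.null(probes)) {
    if (is.null(probe_map) || length(probe_map) != nrow(probes)) {
      fc_abort("probe_map must map every probe row to a gene id")
    }
    genes <- unique(probe_map)
    np <- as.vector(table(probe_map)[genes])
    pm <- rowsum(probes, probe_map)[genes, , drop = FALSE] / np
    # within-gene probe variance per sample
    pv <- (rowsum(probes^2, probe_map)[genes, , drop = FALSE] - np * pm^2) /
      pmax(np - 1, 1)
    se2 <- sweep(pv / np, 2, ctrl_var / n_ctrl, `+`)
    tstat <- sweep(pm, 2, ctrl_mean, `-`) / sqrt(se2)
    # Welch df
    df_num <- se2^2
    df_den <- (pv / np)^2 / pmax(np - 1, 1) +
      matrix(rep((ctrl_var / n_ctrl)^2 / (n_ctrl - 1), each = nrow(pm)),
        nrow(pm))
    dfw <- df_num / df_den
    p <- pt(tstat, dfw, lower.tail = FALSE)
    dimnames(p) <- list(genes, colnames(probes))
  } else {
    expr <- as.matrix(expr)
    z <- sweep(sweep(expr, 2, ctrl_mean, `-`), 2, sqrt(ctrl_var), `/`)
    p <- pnorm(z, lower.tail = FALSE)
    dimnames(p) <- dimnames(expr)
  }
  detected <- p < alpha
  counts <- tibble(
    sample = colnames(p),
    n_detected = unname(colSums(detected)),
    share_pct = round(100 * unname(colMeans(detected)), 2)
  )
  structure(
    list(p = p, detected = detected, counts = counts, alpha = alpha),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %d genes x %d samples, mean detected %.1f%% at alpha = %g\n",
    nrow(x$p), ncol(x$p), mean(100 * colMeans(x$detected)), x$alpha
  ))
  invisible(x)
}

#' @export
tidy.detection_result <- function(x, ...) x$counts

#' Quantile normalization
#'
#' Forces every sample (column) to the identical empirical distribution: the
#' across-sample mean of order statistics, with tied ranks receiving the mean
#' of the corresponding reference values. Delegates to
#' [limma::normalizeQuantiles()]; row/gene identity is preserved.
#'
#' @param mat Genes x samples numeric matrix, at least 2 samples, no missing
#'   values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) fc_abort("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) fc_abort("missing values are not supported")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Delta-Ct prequalification of RNA samples
#'
#' qPCR prequalification: delta-Ct = Ct(test) - Ct(control); lower is better
#' RNA quality. Values up to `pass_threshold` cycles pass; values at most
#' `hard_threshold` are retained as borderline with a warning; anything beyond
#' (or non-finite) fails.
#'
#' @param delta_ct Numeric vector of delta-Ct values (cycles).
#' @param sample Optional sample ids.
#' @param pass_threshold Pass limit (default 12 cycles).
#' @param hard_threshold Borderline limit (default 12.5 cycles).
#' @return Tibble: sample, delta_ct, status in {pass, borderline, fail},
#'   reason.
#' @export
prequalify <- function(delta_ct, sample = NULL,
                       pass_threshold = 12, hard_threshold = 12.5) {
  if (hard_threshold < pass_threshold) {
    fc_abort("hard_threshold must be >= pass_threshold")
  }
  sample <- sample %||% paste0("s", seq_along(delta_ct))
  status <- dplyr::case_when(
    !is.finite(delta_ct) ~ "fail",
    delta_ct <= pass_threshold ~ "pass",
    delta_ct <= hard_threshold ~ "borderline",
    TRUE ~ "fail"
  )
  reason <- dplyr::case_when(
    !is.finite(delta_ct) ~ "non-finite delta-Ct",
    status == "borderline" ~
      sprintf("delta-Ct in (%g, %g]", pass_threshold, hard_threshold),
    status == "fail" ~ sprintf("delta-Ct > %g", hard_threshold),
    TRUE ~ ""
  )
  if (any(status == "borderline")) {
    warn(sprintf(
      "%d sample(s) retained as borderline (delta-Ct just above %g)",
      sum(status == "borderline"), pass_threshold
    ))
  }
  tibble(
    sample = sample, delta_ct = delta_ct,
    status = factor(status, levels = c("pass", "borderline", "fail")),
    reason = reason
  )
}

#' PCA-based sample quality control
#'
#' Projects samples onto the top principal components of the gene-standardized
#' expression matrix and flags outliers whose standardized distance in PC
#' space exceeds `outlier_sd`, or whose detected-gene count falls below
#' `min_detected`.
#'
#' @param mat Normalized genes x samples matrix.
#' @param n_components Number of leading components retained (default 3).
#' @param outlier_sd Distance threshold in component SD units (default 4, so
#'   only gross failures are flagged).
#' @param detected_counts Optional named per-sample detected-gene counts (from
#'   [detection_calls()]).
#' @param min_detected Optional minimum detected-gene count.
#' @return A list of class `qc_result`: `scores` tibble (sample, PC columns,
#'   distance, outlier, reason), `var_share_pct` per retained component,
#'   `sdev` all component SDs.
#' @export
pca_qc <- function(mat, n_components = 3, outlier_sd = 4,
                   detected_counts = NULL, min_detected = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < n_components + 1) {
    fc_abort("need more samples than components")
  }
  sds <- apply(mat, 1, sd)
  if (all(sds == 0)) fc_abort("matrix has no variance")
  keep <- sds > 0
  x <- t((mat[keep, , drop = FALSE] - rowMeans(mat[keep, , drop = FALSE])) /
    sds[keep])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  z <- sweep(scores, 2, pmax(sdev, 1e-12), `/`)
  dist <- sqrt(rowSums(z^2))
  outlier <- dist > outlier_sd
  reason <- ifelse(outlier, sprintf("PC distance %.2f > %g", dist, outlier_sd),
    "")
  if (!is.null(min_detected) && !is.null(detected_counts)) {
    low <- detected_counts[colnames(mat)] < min_detected
    reason <- ifelse(low & !outlier,
      sprintf("only %d genes detected < %d", detected_counts[colnames(mat)],
        min_detected),
      reason)
    outlier <- outlier | low
  }
  tb <- tibble(sample = colnames(mat))
  for (j in seq_len(k)) tb[[paste0("PC", j)]] <- scores[, j]
  tb$distance <- dist
  tb$outlier <- unname(outlier)
  tb$reason <- unname(reason)
  var_share <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tb,
      var_share_pct = var_share[seq_len(k)],
      sdev = pc$sdev
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d samples, %d outlier(s); top components explain %s%%\n",
    nrow(x$scores), sum(x$scores$outlier),
    paste(sprintf("%.1f", x$var_share_pct), collapse = "/")
  ))
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) x$scores
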