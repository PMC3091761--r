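#' Sources-of-variation bar chart
#'
#' Mean F ratio per model term across all genes, the standard summary of
#' which design factor (storage, tissue, person, batch...) dominates
#' expression variability.
#'
#' @param fit A `genefit` (or the tibble from [mean_f_ratio()]).
#' @return A ggplot.
#' @export
plot_sources_of_variation <- function(fit) {
  tb <- if (inherits(fit, "genefit")) mean_f_ratio(fit) else as_tibble(fit)
  ggplot2::ggplot(tb, ggplot2::aes(
    x = stats::reorder(.data$term, -.data$mean_f), y = .data$mean_f
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "source of variation", y = "mean F ratio across genes"
    ) +
    ggplot2::theme_minimal()
}

#' Replicate / paired-sample concordance scatter
#'
#' log2 intensities of one sample against its pair, with the identity line
#' and the two fold-change boundary lines; annotates the squared Pearson
#' correlation.
#'
#' @param x,y Paired log2 vectors.
#' @param fold_boundary Ratio-scale boundary (default 2).
#' @param xlab,ylab Axis labels.
#' @return A ggplot.
#' @export
plot_concordance <- function(x, y, fold_boundary = 2,
                             xlab = "log2 intensity (x)",
                             ylab = "log2 intensity (y)") {
  r2 <- replicate_r2(x, y, fold_boundary)
  b <- log2(fold_boundary)
  ggplot2::ggplot(tibble(x = x, y = y), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = b, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = -b, linetype = 2) +
    ggplot2::labs(
      x = xlab, y = ylab,
      title = sprintf("r² = %.2f (%d beyond %g-fold)",
        r2$r_squared, r2$n_beyond_boundary, fold_boundary)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_qc Scatter of the first two PC scores, outliers
#'   highlighted.
#' @param object A `qc_result`.
#' @param ... Unused.
#' @export
autoplot.qc_result <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(
    .data$PC1, .data$PC2, colour = .data$outlier
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
      `TRUE` = "red")) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$var_share_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$var_share_pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn go_anova Per-gene tissue means of the set members with
#'   standard-error bars (dot-plot view of set-level differential
#'   expression).
#' @param object A `go_anova_record`.
#' @param ... Unused.
#' @export
autoplot.go_anova_record <- function(object, ...) {
  ggplot2::ggplot(object$gene_means, ggplot2::aes(
    x = .data$gene, y = .data$mean, colour = .data$tissue
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(
      x = NULL, y = "log2 expression",
      title = sprintf("%s (%d genes)", object$set, object$n_genes)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Volcano plot of a fitted term
#'
#' @param fit A `genefit`.
#' @param term Model term to display.
#' @param fdr_level,fc_cutoff Selection thresholds to highlight.
#' @return A ggplot.
#' @export
plot_volcano <- function(fit, term, fdr_level = 0.05, fc_cutoff = 2) {
  tb <- dplyr::filter(tidy(fit), .data$term == !!term)
  if (all(is.na(tb$log2_diff))) fc_abort("term has no fold-change contrast")
  tb$selected <- !is.na(tb$q.value) & tb$q.value <= fdr_level &
    abs(tb$fold_change) >= fc_cutoff
  ggplot2::ggplot(tb, ggplot2::aes(
    .data$log2_diff, -log10(.data$p.value), colour = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
      `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 difference", y = "-log10 p", title = term) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
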