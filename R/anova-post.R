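#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up false-discovery-rate adjustment: q(i) is the smallest
#' level at which the i-th smallest p-value would be declared significant.
#' Monotone in p and bounded by 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; non-finite values are an
#'   error.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p))) fc_abort("p-values must be finite")
  if (any(p < 0 | p > 1)) fc_abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# NA-tolerant variant used by tidiers: NA in, NA out
bh_fdr_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (any(ok)) q[ok] <- bh_fdr(p[ok])
  q
}

#' Signed fold change from log2 least-squares means
#'
#' Returns `2^d` for a log2 difference `d = a - b >= 0` and `-2^(-d)`
#' otherwise (signed-reciprocal convention: -2 means 2-fold down). A
#' difference of zero gives +1.
#'
#' @param ls_mean_a,ls_mean_b log2-scale group means (vectors recycle).
#' @return Signed fold change(s).
#' @export
fold_change <- function(ls_mean_a, ls_mean_b) {
  d <- ls_mean_a - ls_mean_b
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Select differentially expressed genes at an FDR and fold-change cutoff
#'
#' Keeps genes whose BH q-value for `term` is at most `fdr_level` and whose
#' absolute fold change is at least `fc_cutoff`, split into up- and
#' down-regulated directions by the sign of the fold change.
#'
#' @param fit A `genefit` from [genomewide_anova()], or a tibble in the shape
#'   of [tidy.genefit()].
#' @param term Model term to select on.
#' @param fdr_level FDR threshold (default 0.05).
#' @param fc_cutoff Minimum |fold change| on the ratio scale (default 2;
#'   `1` collapses the criterion to FDR alone).
#' @param fc_term Term whose fold change is used (defaults to `term`; pass a
#'   different two-level factor when selecting on an interaction).
#' @return A tibble of class `gene_list`: gene, p.value, q.value, log2_diff,
#'   fold_change, direction, ordered by p-value; attribute `label` carries
#'   the selection criteria.
#' @export
select_differential <- function(fit, term, fdr_level = 0.05, fc_cutoff = 2,
                                fc_term = term) {
  tb <- if (inherits(fit, "genefit")) tidy(fit) else as_tibble(fit)
  if (!term %in% tb$term) fc_abort(sprintf("unknown term '%s'", term))
  if (fdr_level <= 0 || fdr_level > 1) fc_abort("fdr_level must be in (0, 1]")
  if (fc_cutoff < 1) fc_abort("fc_cutoff must be >= 1")
  sel <- dplyr::filter(tb, .data$term == !!term)
  if (!"fold_change" %in% names(sel) || all(is.na(sel$fold_change))) {
    fcs <- dplyr::filter(tb, .data$term == !!fc_term)
    sel$fold_change <- fcs$fold_change[match(sel$gene, fcs$gene)]
    sel$log2_diff <- fcs$log2_diff[match(sel$gene, fcs$gene)]
  }
  no_fc <- all(is.na(sel$fold_change))
  out <- sel |>
    dplyr::filter(
      !is.na(.data$q.value), .data$q.value <= fdr_level,
      if (no_fc || fc_cutoff == 1) TRUE else abs(.data$fold_change) >= fc_cutoff
    ) |>
    dplyr::mutate(direction = dplyr::if_else(
      is.na(.data$fold_change) | .data$fold_change >= 0, "up", "down"
    )) |>
    dplyr::arrange(.data$p.value) |>
    dplyr::select("gene", "p.value", "q.value", "log2_diff", "fold_change",
      "direction")
  attr(out, "label") <- sprintf(
    "%s: FDR <= %g, |FC| >= %g", term, fdr_level, fc_cutoff
  )
  class(out) <- c("gene_list", class(out))
  out
}

#' Per-gene percent of variance explained by each model term
#'
#' Every model term (fixed terms included, matching the reporting convention
#' of genomic ANOVA suites) is treated as a variance component in a full
#' method-of-moments equating of all sequential mean squares; negative
#' solutions are truncated at zero and the components are normalized to sum
#' to 100% per gene. A zero-variance gene is 100% residual by convention.
#'
#' @param fit A `genefit`.
#' @return Tibble: gene, term (model terms plus "residual"), pct.
#' @export
variance_partition <- function(fit) {
  if (!inherits(fit, "genefit")) fc_abort("expected a genefit object")
  fit$pct_var
}

#' Mean F-ratio per term across genes (sources-of-variation summary)
#'
#' The across-gene arithmetic mean of each term's F statistic, the standard
#' "which design factor dominates expression variability" summary. Non-finite
#' F values are excluded and counted.
#'
#' @param fit A `genefit` (or tidy tibble with `term` and `statistic`).
#' @return Tibble: term, mean_f, n_genes, n_excluded.
#' @export
mean_f_ratio <- function(fit) {
  tb <- if (inherits(fit, "genefit")) fit$table else as_tibble(fit)
  tb |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(
      mean_f = mean(.data$statistic[is.finite(.data$statistic)]),
      n_genes = sum(is.finite(.data$statistic)),
      n_excluded = sum(!is.finite(.data$statistic)),
      .groups = "drop"
    ) |>
    dplyr::mutate(term = factor(.data$term, levels = unique(tb$term))) |>
    dplyr::arrange(.data$term) |>
    dplyr::mutate(term = as.character(.data$term))
}
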