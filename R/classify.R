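# ---- classifiers -----------------------------------------------------------
# All three classifiers operate on samples-in-rows feature matrices built
# from the genes x samples expression matrix.

# 1-nearest-neighbour, Euclidean; exact distance ties resolved in favour of
# the smallest training-sample index (deterministic)
knn1_predict <- function(train, train_labels, test) {
  d2 <- outer(rowSums(test^2), rowSums(train^2), `+`) -
    2 * tcrossprod(test, train)
  idx <- apply(d2, 1, which.min) # which.min takes the first = smallest index
  train_labels[idx]
}

nearest_centroid_predict <- function(train, train_labels, test) {
  labs <- levels(factor(train_labels))
  cent <- t(vapply(labs, function(l) {
    colMeans(train[train_labels == l, , drop = FALSE])
  }, numeric(ncol(train))))
  d2 <- outer(rowSums(test^2), rowSums(cent^2), `+`) -
    2 * tcrossprod(test, cent)
  labs[apply(d2, 1, which.min)]
}

# linear discriminant with equal priors; the pooled covariance is blended
# toward its diagonal (shrinkage intensity lambda) so p >> n stays invertible
lda_shrink_predict <- function(train, train_labels, test, lambda = 0.5) {
  labs <- levels(factor(train_labels))
  if (length(labs) != 2) fc_abort("shrinkage LDA supports two classes")
  mu <- lapply(labs, function(l) {
    colMeans(train[train_labels == l, , drop = FALSE])
  })
  centered <- train
  for (i in seq_along(labs)) {
    rows <- train_labels == labs[i]
    centered[rows, ] <- sweep(train[rows, , drop = FALSE], 2, mu[[i]])
  }
  pool <- crossprod(centered) / (nrow(train) - length(labs))
  s <- (1 - lambda) * pool + lambda * diag(diag(pool), ncol(pool))
  diag(s) <- diag(s) + 1e-8 * mean(diag(s)) + 1e-12
  diff <- mu[[2]] - mu[[1]]
  w <- solve(s, diff)
  mid <- as.numeric((mu[[1]] + mu[[2]]) %*% w) / 2
  scores <- as.vector(test %*% w)
  ifelse(scores > mid, labs[2], labs[1])
}

classify_fun <- function(classifier, lambda = 0.5) {
  switch(classifier,
    knn1 = knn1_predict,
    nearest_centroid = nearest_centroid_predict,
    lda = function(train, labels, test) {
      lda_shrink_predict(train, labels, test, lambda = lambda)
    },
    fc_abort(sprintf("unknown classifier '%s'", classifier))
  )
}

# stratified, seeded fold assignment
stratified_folds <- function(labels, k, seed) {
  set.seed(child_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- sample(which(labels == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validation specification
#'
#' @param classifier One of `"knn1"` (1-nearest-neighbour, Euclidean),
#'   `"nearest_centroid"` (equal priors) or `"lda"` (linear discriminant with
#'   diagonal-shrinkage pooled covariance, equal priors).
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 10).
#' @param feature_counts Candidate numbers of top-ranked genes; `Inf` means
#'   all genes. In nested mode the inner cross-validation picks the count; in
#'   one-level mode the first value is used.
#' @param select_term ANOVA term used to rank genes for selection.
#' @param select_spec [model_spec()] used for the ranking ANOVA (default:
#'   storage adjusted for tissue and person, the three-way model).
#' @param nested Use two-level nested cross-validation (default `TRUE`).
#' @param lambdas Shrinkage candidates for `"lda"`; the inner loop picks one
#'   (one-level mode uses the first value).
#' @param seed Integer seed for fold construction.
#' @return A `cv_spec`.
#' @export
cv_spec <- function(classifier = c("knn1", "nearest_centroid", "lda"),
                    outer_folds = 10, inner_folds = 10,
                    feature_counts = c(50, 100, Inf),
                    select_term = "storage",
                    select_spec = model_spec(
                      c("tissue", "storage", "case"), random = "case"
                    ),
                    nested = TRUE,
                    lambdas = c(0.25, 0.5, 0.75),
                    seed = 1L) {
  classifier <- match.arg(classifier)
  if (outer_folds < 2 || inner_folds < 2) fc_abort("folds must be >= 2")
  if (any(feature_counts < 1)) fc_abort("feature counts must be >= 1")
  structure(
    list(
      classifier = classifier, outer_folds = outer_folds,
      inner_folds = inner_folds, feature_counts = feature_counts,
      select_term = select_term, select_spec = select_spec,
      nested = nested, lambdas = lambdas, seed = as.integer(seed)
    ),
    class = "cv_spec"
  )
}

#' Rank and select the top genes on training data only
#'
#' Genes are ranked by the selected term's p-value (ascending) from
#' [genomewide_anova()] fitted on the training subset; ties are broken by
#' larger absolute fold change, then lexicographic gene id. A leakage guard
#' errors if any held-out test sample id appears in the training sheet.
#'
#' @param train_mat Genes x training-samples matrix.
#' @param train_sheet Sample sheet restricted to the training samples.
#' @param term Ranking term.
#' @param k Number of genes to keep (`Inf` = all).
#' @param spec [model_spec()] for the ranking ANOVA.
#' @param test_ids Held-out sample ids; their presence in `train_sheet` is an
#'   error.
#' @return Character vector of the top `k` gene ids.
#' @export
select_features_for_cv <- function(train_mat, train_sheet, term, k,
                                   spec = model_spec(
                                     c("tissue", "storage", "case"),
                                     random = "case"
                                   ),
                                   test_ids = NULL) {
  if (!is.null(test_ids) &&
    length(intersect(test_ids, train_sheet$sample)) > 0) {
    fc_abort("leakage: held-out test samples present in the training sheet")
  }
  if (is.finite(k) && k > nrow(train_mat)) {
    fc_abort("k exceeds the number of genes")
  }
  if (!is.finite(k) || k == nrow(train_mat)) return(rownames(train_mat))
  fit <- genomewide_anova(train_mat, train_sheet, spec)
  tb <- dplyr::filter(fit$table, .data$term == !!term)
  fcs <- fit$fold_changes
  afc <- if (!is.null(fcs) && term %in% fcs$factor) {
    abs(fcs$fold_change[fcs$factor == term][match(tb$gene, fcs$gene[fcs$factor == term])])
  } else {
    rep(0, nrow(tb))
  }
  ord <- order(tb$p.value, -afc, tb$gene)
  tb$gene[ord][seq_len(k)]
}

#' Cross-validated classification accuracy
#'
#' One-level mode: stratified k-fold cross-validation in which every modeling
#' step, including gene ranking and selection, is refit inside each training
#' fold. Nested mode (two-level): within each outer training set an inner
#' cross-validation chooses the feature count (and the LDA shrinkage
#' intensity) maximizing inner accuracy; the chosen configuration is refit on
#' the full outer training set and scored on the held-out outer fold, giving
#' the reported overall accuracy.
#'
#' @param mat Genes x samples log2 matrix.
#' @param sheet Sample sheet (needs `sample` plus the factors of
#'   `spec$select_spec`).
#' @param label_col Sheet column holding the two-class label (default
#'   `"storage"`).
#' @param spec A [cv_spec()].
#' @return A list of class `cv_result`: `accuracy_pct` (overall, two
#'   decimals), `n_correct`, `n_total`, `folds` (per-fold tibble with chosen
#'   feature count and lambda), `confusion` (table), `spec`.
#' @export
cross_validate <- function(mat, sheet, label_col = "storage", spec = cv_spec()) {
  mat <- as.matrix(mat)
  sheet <- as.data.frame(sheet)
  if (!label_col %in% names(sheet)) {
    fc_abort(sprintf("label column '%s' not in sheet", label_col))
  }
  labels <- as.character(sheet[[label_col]])
  if (length(unique(labels)) < 2) fc_abort("need at least two classes")
  n <- ncol(mat)
  if (n < spec$outer_folds) fc_abort("more folds than samples")
  if (min(table(labels)) < spec$outer_folds) {
    warn("a class has fewer samples than folds; some folds lack that class")
  }
  x <- t(mat) # samples x genes

  fold <- stratified_folds(labels, spec$outer_folds, spec$seed)
  if (any(vapply(seq_len(spec$outer_folds), function(f) {
    length(unique(labels[fold != f])) < 2
  }, logical(1)))) {
    fc_abort("stratification error: a class is absent from a training fold")
  }

  lambdas <- if (spec$classifier == "lda") spec$lambdas else NA_real_

  eval_config <- function(train_idx, test_idx, k, lambda) {
    feats <- select_features_for_cv(
      mat[, train_idx, drop = FALSE],
      sheet[train_idx, , drop = FALSE],
      term = spec$select_term, k = min(k, nrow(mat)),
      spec = spec$select_spec,
      test_ids = sheet$sample[test_idx]
    )
    fun <- classify_fun(spec$classifier,
      lambda = if (is.na(lambda)) 0.5 else lambda)
    pred <- fun(
      x[train_idx, feats, drop = FALSE], labels[train_idx],
      x[test_idx, feats, drop = FALSE]
    )
    pred == labels[test_idx]
  }

  fold_rows <- list()
  correct <- logical(n)
  pred_all <- character(n)
  for (f in seq_len(spec$outer_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (length(test_idx) == 0) next
    if (spec$nested) {
      inner_fold <- stratified_folds(labels[train_idx], spec$inner_folds,
        spec$seed + f)
      grid <- expand.grid(k = spec$feature_counts, lambda = lambdas)
      inner_acc <- vapply(seq_len(nrow(grid)), function(gi) {
        ok <- unlist(lapply(seq_len(spec$inner_folds), function(g) {
          it <- train_idx[inner_fold == g]
          tr <- train_idx[inner_fold != g]
          if (length(it) == 0 || length(unique(labels[tr])) < 2) {
            return(logical(0))
          }
          eval_config(tr, it, grid$k[gi], grid$lambda[gi])
        }))
        mean(ok)
      }, 0)
      best <- which.max(inner_acc) # first maximum: smallest feature count
      k_star <- grid$k[best]
      lambda_star <- grid$lambda[best]
    } else {
      k_star <- spec$feature_counts[1]
      lambda_star <- lambdas[1]
    }
    ok <- eval_config(train_idx, test_idx, k_star, lambda_star)
    correct[test_idx] <- ok
    fold_rows[[f]] <- tibble(
      fold = f, n_test = length(test_idx),
      feature_count = k_star, lambda = lambda_star,
      accuracy_pct = round(100 * mean(ok), 2)
    )
  }
  acc <- 100 * mean(correct)
  structure(
    list(
      accuracy_pct = round(acc, 2),
      n_correct = sum(correct), n_total = n,
      folds = dplyr::bind_rows(fold_rows),
      spec = spec, label_col = label_col
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, %s: overall accuracy %.2f%% (%d/%d)\n",
    x$spec$classifier,
    if (x$spec$nested) "nested 10x10-style CV" else "one-level CV",
    x$accuracy_pct, x$n_correct, x$n_total
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    classifier = x$spec$classifier, nested = x$spec$nested,
    accuracy_pct = x$accuracy_pct,
    n_correct = x$n_correct, n_total = x$n_total
  )
}

#' Cross-validated accuracy of an external gene signature
#'
#' Restricts the feature space to a fixed signature (no in-loop selection)
#' and reports stratified k-fold accuracy as a two-decimal percentage
#' alongside the raw correct/total counts (the counts are the primary
#' record; percentages depend on rounding conventions).
#'
#' @param mat Genes x samples log2 matrix.
#' @param labels Class label per sample.
#' @param signature Character vector of signature gene ids; ids absent from
#'   the matrix are dropped with a reported count.
#' @param classifier As in [cv_spec()] (default nearest centroid).
#' @param folds Fold count (default 10).
#' @param seed Fold seed.
#' @return Tibble: n_signature, n_used, n_dropped, n_correct, n_total,
#'   accuracy_pct.
#' @export
signature_predict <- function(mat, labels, signature,
                              classifier = "nearest_centroid",
                              folds = 10, seed = 1L) {
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  present <- intersect(unique(signature), rownames(mat))
  dropped <- length(unique(signature)) - length(present)
  if (length(present) == 0) fc_abort("no signature gene present in the matrix")
  x <- t(mat[present, , drop = FALSE])
  fold <- stratified_folds(labels, min(folds, length(labels)), seed)
  fun <- classify_fun(classifier)
  correct <- logical(length(labels))
  for (f in sort(unique(fold))) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    pred <- fun(x[train_idx, , drop = FALSE], labels[train_idx],
      x[test_idx, , drop = FALSE])
    correct[test_idx] <- pred == labels[test_idx]
  }
  tibble(
    n_signature = length(unique(signature)),
    n_used = length(present), n_dropped = dropped,
    n_correct = sum(correct), n_total = length(labels),
    accuracy_pct = round(100 * mean(correct), 2)
  )
}

#' Venn overlap between named gene lists
#'
#' Identical machinery to [setlist_overlap()], exposed for gene-level lists:
#' all Venn region counts plus pairwise shared counts and shares of each
#' list.
#'
#' @param lists Named list (>= 2) of character vectors (or `gene_list`
#'   tibbles).
#' @return An `overlap_report`.
#' @export
list_overlap <- function(lists) {
  lists <- lapply(lists, function(l) {
    if (is.data.frame(l)) l$gene else as.character(l)
  })
  setlist_overlap(lists)
}

#' Replicate concordance: squared correlation and fold-change outliers
#'
#' Squared Pearson correlation between two paired log2 intensity vectors,
#' plus the number of genes whose absolute log2 difference strictly exceeds
#' the fold-change boundary (default 2-fold, i.e. |x - y| > 1 on the log2
#' scale).
#'
#' @param x,y Paired log2 vectors of equal length >= 3.
#' @param fold_boundary Ratio-scale boundary (default 2).
#' @return Tibble: n, r_squared, n_beyond_boundary, fold_boundary.
#' @export
replicate_r2 <- function(x, y, fold_boundary = 2) {
  if (length(x) != length(y)) fc_abort("x and y must have equal length")
  if (length(x) < 3) fc_abort("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) fc_abort("zero-variance vector")
  r2 <- cor(x, y)^2
  beyond <- sum(abs(x - y) > log2(fold_boundary))
  tibble(
    n = length(x), r_squared = r2,
    n_beyond_boundary = beyond, fold_boundary = fold_boundary
  )
}

#' Standardized effect size for power planning
#'
#' The dimensionless effect size `log2(fold_change) / sigma` used in
#' FDR-based sample-size calculations: a 2-fold change with a log2-scale SD
#' of 0.5 gives 2.
#'
#' @param fold_change Ratio-scale fold change (> 0).
#' @param sigma log2-scale standard deviation (> 0).
#' @return `log2(fold_change) / sigma`.
#' @export
standardized_effect_size <- function(fold_change, sigma) {
  if (any(fold_change <= 0)) fc_abort("fold_change must be positive")
  if (any(sigma <= 0)) fc_abort("sigma must be positive")
  log2(fold_change) / sigma
}
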