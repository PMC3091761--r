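#' Specify a per-gene ANOVA model
#'
#' Declares the model terms in fitting order (sums of squares are sequential,
#' Type I), which factors are random, and which enter as linear covariates.
#' Interaction terms are written `"a:b"` and must reference declared main
#' terms. The two canonical specifications of a paired FF/FFPE study are
#' available as [spec_combined()] (tissue + storage + case + tissue:storage,
#' case random) and [spec_within_storage()] (tissue + batch + block_age, batch
#' random, block_age a covariate).
#'
#' @param terms Character vector of term names in fitting order. Categorical
#'   terms must be factor columns of the sample sheet.
#' @param random Character vector naming the random terms (subset of `terms`).
#' @param covariates Character vector naming terms that enter as 1-df linear
#'   slopes.
#' @return A `model_spec`.
#' @export
model_spec <- function(terms, random = character(), covariates = character()) {
  if (length(terms) == 0) fc_abort("at least one model term is required")
  if (!all(random %in% terms)) fc_abort("random terms must be declared terms")
  if (!all(covariates %in% terms)) {
    fc_abort("covariates must be declared terms")
  }
  if (length(intersect(random, covariates))) {
    fc_abort("a term cannot be both random and a covariate")
  }
  inter <- grepl(":", terms, fixed = TRUE)
  comp <- unique(unlist(strsplit(terms[inter], ":", fixed = TRUE)))
  if (!all(comp %in% terms[!inter])) {
    fc_abort("interaction terms must reference declared main terms")
  }
  structure(
    list(terms = terms, random = random, covariates = covariates),
    class = "model_spec"
  )
}

#' @rdname model_spec
#' @export
spec_combined <- function() {
  model_spec(
    terms = c("tissue", "storage", "case", "tissue:storage"),
    random = "case"
  )
}

#' @rdname model_spec
#' @export
spec_within_storage <- function() {
  model_spec(
    terms = c("tissue", "batch", "block_age"),
    random = "batch",
    covariates = "block_age"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- vapply(x$terms, function(t) {
    if (t %in% x$random) paste0(t, " (random)")
    else if (t %in% x$covariates) paste0(t, " (covariate)")
    else t
  }, "")
  cat("<model_spec> y ~", paste(lab, collapse = " + "), "\n")
  invisible(x)
}

# ---- design machinery ------------------------------------------------------

# indicator columns for one term evaluated on a data frame
term_columns <- function(term, data, spec) {
  if (term %in% spec$covariates) {
    x <- data[[term]]
    if (!is.numeric(x)) fc_abort(sprintf("covariate '%s' must be numeric", term))
    return(matrix(x, ncol = 1))
  }
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  f <- if (length(parts) == 1) {
    data[[parts]]
  } else {
    interaction(data[parts], drop = FALSE, sep = ":")
  }
  if (is.null(f)) fc_abort(sprintf("term '%s' not found in sample sheet", term))
  f <- as.factor(f)
  stats::model.matrix(~ 0 + f)
}

# Precompute, for a realized design, everything the per-gene fits reuse:
# sequential projection differences Q_t, their dfs, EMS coefficient matrices
# (from quadratic-form traces), synthesized F-denominator weights, and
# LS-mean extraction matrices.
anova_design <- function(sheet, spec) {
  sheet <- as.data.frame(sheet)
  for (t in setdiff(spec$terms, spec$covariates)) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    for (v in parts) {
      if (!v %in% names(sheet)) {
        fc_abort(sprintf("factor '%s' not found in sample sheet", v))
      }
      if (!is.factor(sheet[[v]])) sheet[[v]] <- factor(sheet[[v]])
      lev <- levels(sheet[[v]])
      if (any(table(sheet[[v]]) == 0)) {
        sheet[[v]] <- droplevels(sheet[[v]])
      }
    }
  }
  n <- nrow(sheet)
  terms <- spec$terms
  nt <- length(terms)

  X <- matrix(1, n, 1) # intercept
  rank_prev <- 1L
  qr_prev <- qr(X)
  P_prev <- tcrossprod(qr.Q(qr_prev)[, seq_len(rank_prev), drop = FALSE])
  Q_list <- vector("list", nt)
  df <- integer(nt)
  for (i in seq_len(nt)) {
    X <- cbind(X, term_columns(terms[i], sheet, spec))
    qr_cur <- qr(X)
    r <- qr_cur$rank
    P_cur <- tcrossprod(qr.Q(qr_cur)[, seq_len(r), drop = FALSE])
    Q_list[[i]] <- P_cur - P_prev
    df[i] <- r - rank_prev
    P_prev <- P_cur
    rank_prev <- r
  }
  Q_res <- diag(n) - P_prev
  df_res <- n - rank_prev
  if (df_res <= 0) fc_abort("design is saturated: no residual degrees of freedom")
  X_full <- X
  qr_full <- qr_cur

  # quadratic-form kernels for every term treated as a variance component
  G_list <- lapply(seq_len(nt), function(i) {
    t <- terms[i]
    if (t %in% spec$covariates) {
      x <- sheet[[t]] - mean(sheet[[t]])
      v <- sum(x^2) / (n - 1)
      if (v <= 0) return(matrix(0, n, n))
      tcrossprod(x) / v
    } else {
      Z <- term_columns(t, sheet, spec)
      tcrossprod(Z)
    }
  })

  trQG <- function(Q, G) sum(Q * G) # both symmetric

  # full EMS system over all terms (for variance partitioning)
  C_full <- matrix(0, nt + 1, nt + 1,
    dimnames = list(c(terms, "residual"), c(terms, "residual"))
  )
  for (i in seq_len(nt)) {
    if (df[i] == 0) next
    for (j in seq_len(nt)) C_full[i, j] <- trQG(Q_list[[i]], G_list[[j]]) / df[i]
    C_full[i, nt + 1] <- 1
  }
  for (j in seq_len(nt)) {
    C_full[nt + 1, j] <- trQG(Q_res, G_list[[j]]) / df_res
  }
  C_full[nt + 1, nt + 1] <- 1

  # restricted system over the declared random components + residual,
  # equated on the random terms' and residual mean squares (MoM proper)
  rand_idx <- match(spec$random, terms)
  comp_names <- c(spec$random, "residual")
  C_rand <- C_full[
    c(rand_idx, nt + 1), c(rand_idx, nt + 1),
    drop = FALSE
  ]

  # F-test denominator weights per term: express the null expectation of
  # MS_t (its EMS minus its own component) in the basis of the random-term
  # and residual mean squares
  ms_rows <- c(rand_idx, NA_integer_) # NA marks residual
  denom_w <- matrix(0, nt, length(comp_names),
    dimnames = list(terms, comp_names)
  )
  for (i in seq_len(nt)) {
    if (df[i] == 0) next
    d <- c(C_full[i, rand_idx], 1) # coefficients on (sigma2_rand..., sigma2_e)
    if (terms[i] %in% spec$random) {
      d[match(terms[i], spec$random)] <- 0 # drop own component under H0
    }
    w <- tryCatch(solve(t(C_rand), d), error = function(e) NULL)
    if (is.null(w)) { # fall back to residual MS
      w <- c(rep(0, length(rand_idx)), 1)
    }
    denom_w[i, ] <- w
  }

  # LS-mean machinery: balanced reference grid over all categorical factors,
  # covariates at their observed mean
  cat_terms <- setdiff(terms, c(spec$covariates, terms[grepl(":", terms)]))
  fixed_cat <- setdiff(cat_terms, spec$random)
  grid_vars <- cat_terms
  lsmean_ops <- list()
  if (length(grid_vars)) {
    grid <- expand.grid(
      lapply(sheet[grid_vars], function(f) factor(levels(f), levels(f))),
      KEEP.OUT.ATTRS = FALSE
    )
    names(grid) <- grid_vars
    for (cv in spec$covariates) grid[[cv]] <- mean(sheet[[cv]])
    Xg <- matrix(1, nrow(grid), 1)
    for (t in terms) Xg <- cbind(Xg, term_columns(t, grid, spec))
    # minimum-norm OLS coefficients: beta = ginv(X'X) X' y
    Gmat <- MASS::ginv(crossprod(X_full)) %*% t(X_full) # p x n
    Pg <- Xg %*% Gmat # grid x n: predictions = Pg %*% y
    for (f in fixed_cat) {
      lev <- levels(sheet[[f]])
      M <- vapply(lev, function(l) as.numeric(grid[[f]] == l) /
          sum(grid[[f]] == l), numeric(nrow(grid)))
      lsmean_ops[[f]] <- list(levels = lev, A = t(M) %*% Pg) # levels x n
    }
  }

  list(
    sheet = sheet, spec = spec, n = n,
    terms = terms, df = df, df_res = df_res,
    Q_list = Q_list, Q_res = Q_res,
    C_full = C_full, C_rand = C_rand, comp_names = comp_names,
    denom_w = denom_w, rand_idx = rand_idx,
    lsmean_ops = lsmean_ops
  )
}

#' Genome-wide per-gene mixed-model ANOVA
#'
#' Fits the declared model to every gene's log2 intensities by sequential
#' (Type I) decomposition. Variance components for the random terms are
#' obtained by method of moments: the observed mean squares of the random
#' terms and the residual are equated to their expected mean squares, whose
#' coefficients are computed numerically from the realized design via
#' quadratic-form traces (so unbalanced designs, e.g. after excluding a QC
#' outlier, are handled without balanced-case formulas). Negative solutions
#' are truncated to zero with the raw value retained. Each term's F uses the
#' EMS-implied denominator: the residual mean square when no random component
#' enters its null expectation, otherwise a synthesized linear combination of
#' mean squares with Satterthwaite degrees of freedom.
#'
#' No gene filtering is applied before fitting.
#'
#' @param mat Genes x samples matrix of log2 intensities; columns must match
#'   `sheet$sample` (reordered if necessary).
#' @param sheet Sample sheet (tibble/data.frame) with a `sample` column and
#'   the model factors.
#' @param spec A [model_spec()].
#' @return An object of class `genefit` with per-gene tables; see
#'   [tidy.genefit()], [variance_partition()], [select_differential()].
#' @export
genomewide_anova <- function(mat, sheet, spec) {
  mat <- rbind(as.matrix(mat)) # keeps 1-row input a matrix
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (!is.null(sheet$sample) && !is.null(colnames(mat))) {
    if (!setequal(colnames(mat), sheet$sample)) {
      fc_abort("matrix samples do not match the sample sheet")
    }
    mat <- mat[, as.character(sheet$sample), drop = FALSE]
  } else if (ncol(mat) != nrow(sheet)) {
    fc_abort("matrix samples do not match the sample sheet")
  }
  dsn <- anova_design(sheet, spec)
  genes <- rownames(mat)
  ng <- nrow(mat)
  nt <- length(dsn$terms)

  ss <- matrix(0, ng, nt + 1, dimnames = list(genes, c(dsn$terms, "residual")))
  for (i in seq_len(nt)) {
    ss[, i] <- rowSums((mat %*% dsn$Q_list[[i]]) * mat)
  }
  ss[, nt + 1] <- rowSums((mat %*% dsn$Q_res) * mat)
  ss[ss < 0] <- 0 # numerical negatives from the projection arithmetic
  # constant genes: projection round-off leaves O(eps) sums of squares that
  # would otherwise masquerade as structure
  scale <- rowSums(mat * mat)
  zero_var <- rowSums(ss) <= 1e-10 * pmax(scale, 1)
  ss[zero_var, ] <- 0

  dfv <- c(dsn$df, dsn$df_res)
  ms <- sweep(ss, 2, ifelse(dfv > 0, dfv, NA_real_), `/`)

  # method-of-moments components for the declared random terms
  ms_rand <- ms[, c(dsn$rand_idx, nt + 1), drop = FALSE]
  comp_raw <- t(solve(dsn$C_rand, t(ms_rand)))
  colnames(comp_raw) <- dsn$comp_names
  comp <- pmax(comp_raw, 0)

  # F statistics with synthesized denominators
  Fm <- matrix(NA_real_, ng, nt, dimnames = list(genes, dsn$terms))
  Pm <- Fm
  df_den <- Fm
  for (i in seq_len(nt)) {
    if (dsn$df[i] == 0) next
    w <- dsn$denom_w[i, ]
    denom <- as.vector(ms_rand %*% w)
    dfj <- c(dsn$df[dsn$rand_idx], dsn$df_res)
    contrib <- sweep(ms_rand, 2, w, `*`)
    sat <- denom^2 / rowSums(sweep(contrib^2, 2, ifelse(dfj > 0, dfj, NA), `/`),
      na.rm = TRUE)
    zero <- denom <= 0
    Fm[, i] <- ifelse(zero, NA_real_, ms[, i] / denom)
    df_den[, i] <- sat
    Pm[, i] <- pf(Fm[, i], dsn$df[i], sat, lower.tail = FALSE)
  }

  # variance partition via the full equating (all terms as components)
  est_full <- t(solve(dsn$C_full, t(ms)))
  est_full[!is.finite(est_full)] <- 0
  est_full <- pmax(est_full, 0)
  tot <- rowSums(est_full)
  pct <- 100 * est_full / ifelse(tot > 0, tot, 1)
  pct[tot == 0, ] <- 0
  pct[tot == 0, nt + 1] <- 100 # zero-variance genes: all residual by convention

  # LS-means and per-factor fold changes for 2-level fixed factors
  lsmeans <- NULL
  fold <- NULL
  if (length(dsn$lsmean_ops)) {
    ls_list <- lapply(names(dsn$lsmean_ops), function(f) {
      op <- dsn$lsmean_ops[[f]]
      vals <- mat %*% t(op$A) # genes x levels
      tibble(
        gene = rep(genes, length(op$levels)),
        factor = f,
        level = rep(op$levels, each = ng),
        lsmean = as.vector(vals)
      )
    })
    lsmeans <- dplyr::bind_rows(ls_list)
    fc_list <- lapply(names(dsn$lsmean_ops), function(f) {
      op <- dsn$lsmean_ops[[f]]
      if (length(op$levels) != 2) return(NULL)
      vals <- mat %*% t(op$A)
      d <- vals[, 2] - vals[, 1]
      tibble(
        gene = genes, factor = f,
        contrast = paste(op$levels[2], "vs", op$levels[1]),
        log2_diff = unname(d),
        fold_change = fold_change(d, 0)
      )
    })
    fold <- dplyr::bind_rows(fc_list)
  }

  table <- tibble(
    gene = rep(genes, nt),
    term = rep(dsn$terms, each = ng),
    df = rep(dsn$df, each = ng),
    sumsq = as.vector(ss[, seq_len(nt)]),
    meansq = as.vector(ms[, seq_len(nt)]),
    statistic = as.vector(Fm),
    df_denom = as.vector(df_den),
    p.value = as.vector(Pm)
  )

  structure(
    list(
      table = table,
      components = tibble(
        gene = rep(genes, ncol(comp)),
        component = rep(colnames(comp), each = ng),
        estimate = as.vector(comp),
        raw = as.vector(comp_raw)
      ),
      pct_var = tibble(
        gene = rep(genes, nt + 1),
        term = rep(colnames(pct), each = ng),
        pct = as.vector(pct)
      ),
      lsmeans = lsmeans,
      fold_changes = fold,
      residual = tibble(
        gene = genes, df = dsn$df_res,
        sumsq = ss[, nt + 1], meansq = ms[, nt + 1]
      ),
      spec = spec, n_samples = dsn$n, genes = genes
    ),
    class = "genefit"
  )
}

#' Fit the per-gene mixed ANOVA for a single gene
#'
#' @param y Numeric vector of per-sample log2 values (order of `sheet`).
#' @param sheet Sample sheet.
#' @param spec A [model_spec()].
#' @param gene Row label for the result.
#' @return A `genefit` with one gene.
#' @export
fit_gene_anova <- function(y, sheet, spec, gene = "gene") {
  m <- matrix(y, nrow = 1, dimnames = list(gene, sheet$sample))
  genomewide_anova(m, sheet, spec)
}

#' @export
print.genefit <- function(x, ...) {
  cat(sprintf(
    "<genefit> %d gene(s) x %d sample(s); terms: %s\n",
    length(x$genes), x$n_samples, paste(x$spec$terms, collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a genefit into one row per gene and term
#'
#' Adds Benjamini-Hochberg q-values per term and, where a two-level fixed
#' factor matches the term, its signed fold change.
#'
#' @param x A `genefit`.
#' @param ... Unused.
#' @return A tibble: gene, term, df, sumsq, meansq, statistic, df_denom,
#'   p.value, q.value, log2_diff, fold_change.
#' @export
tidy.genefit <- function(x, ...) {
  tb <- x$table |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(q.value = bh_fdr_na(.data$p.value)) |>
    dplyr::ungroup()
  if (!is.null(x$fold_changes)) {
    tb <- dplyr::left_join(
      tb,
      dplyr::select(x$fold_changes, "gene",
        term = "factor", "log2_diff", "fold_change"),
      by = c("gene", "term")
    )
  }
  tb
}

#' @export
glance.genefit <- function(x, ...) {
  mf <- mean_f_ratio(x)
  tibble(
    n_genes = length(x$genes),
    n_samples = x$n_samples,
    n_terms = length(x$spec$terms),
    top_term = mf$term[which.max(mf$mean_f)],
    max_mean_f = max(mf$mean_f)
  )
}
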