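#' GO-enrichment chi-square scoring of a gene list
#'
#' For each set, compares "significant genes in the category / total
#' significant genes" against "genes on the chip in that category / total
#' genes on the chip" with a 1-df chi-square test (no continuity correction),
#' and reports the enrichment score `-log(p)` used to rank functional groups.
#'
#' @param gene_list Character vector of significant gene ids (or a
#'   `gene_list` from [select_differential()]).
#' @param universe Character vector of all gene ids on the chip.
#' @param sets A [gene_set_collection()]; sets are intersected with the
#'   universe and empty sets skipped.
#' @param log_base Base for the enrichment score: `"e"` (default, natural
#'   log) or `"10"`.
#' @return Tibble sorted by decreasing score: set, n_list_in_set (a),
#'   n_list (b), n_chip_in_set (c), n_chip (d), chisq, p.value, score.
#' @export
go_enrichment <- function(gene_list, universe, sets, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  if (inherits(gene_list, "gene_list") || is.data.frame(gene_list)) {
    gene_list <- gene_list$gene
  }
  gene_list <- unique(as.character(gene_list))
  universe <- unique(as.character(universe))
  if (!all(gene_list %in% universe)) {
    fc_abort("gene_list must be a subset of the universe")
  }
  b <- length(gene_list)
  d <- length(universe)
  if (b == 0) warn("empty gene list: all enrichment scores are 0")
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) == 0) return(NULL)
    a <- length(intersect(gene_list, members))
    cc <- length(members)
    if (b == 0) {
      return(tibble(
        set = nm, n_list_in_set = 0L, n_list = 0L,
        n_chip_in_set = cc, n_chip = d,
        chisq = 0, p.value = 1, score = 0
      ))
    }
    # 2x2 of the two proportions the test compares: the list vs the chip
    tab <- matrix(c(a, b - a, cc, d - cc), 2, byrow = TRUE)
    if (a / b == cc / d) {
      stat <- 0
      p <- 1
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      if (any(ct$expected < 5)) {
        warn(sprintf("set '%s': chi-square expected count < 5", nm))
      }
      stat <- unname(ct$statistic)
      p <- unname(ct$p.value)
    }
    tibble(
      set = nm, n_list_in_set = a, n_list = b,
      n_chip_in_set = cc, n_chip = d,
      chisq = stat, p.value = p,
      score = if (log_base == "e") -log(p) else -log10(p)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$score))
}

# signal-to-noise ranking metric with the classic SD floor
signal_to_noise <- function(mat, is_pos) {
  m1 <- rowMeans(mat[, is_pos, drop = FALSE])
  m0 <- rowMeans(mat[, !is_pos, drop = FALSE])
  s1 <- apply(mat[, is_pos, drop = FALSE], 1, sd)
  s0 <- apply(mat[, !is_pos, drop = FALSE], 1, sd)
  floor_sd <- function(s, m) pmax(s, ifelse(m == 0, 0.2, 0.2 * abs(m)))
  (m1 - m0) / (floor_sd(s1, m1) + floor_sd(s0, m0))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
running_es <- function(metric_ranked, in_set, weight_p) {
  n <- length(metric_ranked)
  nh <- sum(in_set)
  w <- abs(metric_ranked)^weight_p
  nr <- sum(w[in_set])
  hit <- numeric(n)
  hit[in_set] <- if (nr > 0) w[in_set] / nr else 1 / nh
  miss <- numeric(n)
  miss[!in_set] <- 1 / (n - nh)
  run <- cumsum(hit - miss)
  # extremum of maximal magnitude; near-ties (floating noise, or the exact
  # +x/-x tie) resolve to the earliest position
  cand <- which(abs(run) >= max(abs(run)) - 1e-9)
  run[cand[1]]
}

#' Gene set enrichment analysis (GSEA)
#'
#' Ranks genes by the signal-to-noise ratio between two phenotype classes and
#' asks, per set, whether its members concentrate at the top or bottom of the
#' ranking. The enrichment score (ES) is the maximum deviation of the
#' weighted running sum (hit increments proportional to |metric|^`weight_p`,
#' miss decrements 1/(N - |S|)); significance and the normalized score (NES)
#' come from phenotype-label permutation, normalizing by the mean |permuted
#' ES| of matching sign.
#'
#' @param mat Genes x samples log2 matrix.
#' @param labels Two-class phenotype per sample (factor or character), each
#'   class with at least 3 samples.
#' @param sets A [gene_set_collection()].
#' @param n_permutations Phenotype permutations (default 1000; minimum 10).
#' @param seed Integer seed for the permutations.
#' @param weight_p Running-sum weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   matrix's genes (defaults 15 and 500).
#' @param positive_class Which label is the "positive" phenotype for the
#'   metric sign (default: the second factor level). The NES sign convention
#'   follows this orientation.
#' @return Tibble of class `gsea_result`: set, size, es, nes, p.value,
#'   direction; attribute `n_degenerate` counts dropped zero-variance genes.
#' @export
gsea <- function(mat, labels, sets, n_permutations = 1000, seed = 1,
                 weight_p = 1, min_size = 15, max_size = 500,
                 positive_class = NULL) {
  mat <- as.matrix(mat)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) fc_abort("labels must have exactly two classes")
  if (any(table(labels) < 3)) {
    fc_abort("each phenotype class needs at least 3 samples")
  }
  if (n_permutations < 10) fc_abort("need at least 10 permutations")
  positive_class <- positive_class %||% levels(labels)[2]
  if (!positive_class %in% levels(labels)) fc_abort("unknown positive_class")

  degenerate <- apply(mat, 1, var) == 0
  if (any(degenerate)) mat <- mat[!degenerate, , drop = FALSE]
  genes <- rownames(mat)

  members <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  members <- members[keep]
  if (length(members) == 0) {
    fc_abort("no gene set within [min_size, max_size] after intersection")
  }

  es_all <- function(is_pos) {
    metric <- signal_to_noise(mat, is_pos)
    ord <- order(metric, decreasing = TRUE)
    in_rank <- logical(length(genes))
    vapply(members, function(idx) {
      in_rank[] <- FALSE
      in_rank[match(idx, ord)] <- TRUE
      running_es(metric[ord], in_rank, weight_p)
    }, 0)
  }

  is_pos <- labels == positive_class
  es <- es_all(is_pos)

  set.seed(child_seed(seed, "perms"))
  n_samp <- ncol(mat)
  perm_es <- matrix(0, n_permutations, length(members))
  for (b in seq_len(n_permutations)) {
    perm_es[b, ] <- es_all(sample(is_pos, n_samp))
  }

  nes <- p <- rep(NA_real_, length(members))
  for (j in seq_along(members)) {
    same_sign <- if (es[j] >= 0) perm_es[, j] >= 0 else perm_es[, j] < 0
    pool <- perm_es[same_sign, j]
    if (length(pool) > 0) {
      p[j] <- mean(abs(pool) >= abs(es[j]))
      m <- mean(abs(pool))
      if (m > 0) nes[j] <- es[j] / m
    }
  }

  out <- tibble(
    set = names(members), size = lengths(members),
    es = es, nes = nes, p.value = p,
    direction = dplyr::if_else(es >= 0,
      paste0("up in ", positive_class), paste0("down in ", positive_class))
  )
  out <- dplyr::arrange(out, .data$p.value, dplyr::desc(abs(.data$nes)))
  attr(out, "n_degenerate") <- sum(degenerate)
  attr(out, "positive_class") <- positive_class
  class(out) <- c("gsea_result", class(out))
  out
}

#' Set-level mixed-model ANOVA of one gene set (GO-ANOVA)
#'
#' Stacks the member genes' log2 values and fits
#' `Y = mu + T + P + G + S(T*P) + e`, where T is the tissue effect, P the
#' patient effect, G the gene-to-gene effect within the set, and S(T*P) the
#' random sample effect nested in tissue and patient. Set-level differential
#' expression is the T-term test, whose denominator is the sample-to-sample
#' mean square. The fit exploits the complete gene x sample crossing: the
#' sample-stratum terms are estimated on per-sample means of the member genes
#' and scaled back, which is exact for this balanced stacking.
#'
#' A singleton set is fitted without the G and S terms (they would be
#' saturated) and then reduces to the per-gene paired model.
#'
#' @param mat Genes x samples log2 matrix.
#' @param sheet Sample sheet with `sample`, `tissue`, `case` columns.
#' @param set Character vector of member gene ids (or a single-set
#'   [gene_set_collection()]).
#' @param set_name Label for the result.
#' @return A list of class `go_anova_record`: `set`, `n_genes`, `anova`
#'   (tibble of T/P/G/S terms with df, sumsq, meansq, statistic, p.value),
#'   `components` (variance components for P, G, S(T*P), residual),
#'   `gene_means` (per gene x tissue mean and SE for dot plots).
#' @export
go_anova <- function(mat, sheet, set, set_name = "set") {
  if (inherits(set, "gene_set_collection")) {
    set_name <- names(set)[1]
    set <- set[[1]]
  }
  mat <- as.matrix(mat)
  members <- intersect(set, rownames(mat))
  if (length(members) == 0) fc_abort("no set member present in the matrix")
  sheet <- as.data.frame(sheet)
  for (v in c("tissue", "case")) {
    if (!v %in% names(sheet)) fc_abort(sprintf("sheet needs a '%s' column", v))
    sheet[[v]] <- droplevels(as.factor(sheet[[v]]))
  }
  sub <- mat[members, as.character(sheet$sample), drop = FALSE]
  g <- nrow(sub)
  n <- ncol(sub)

  if (g == 1) {
    fit <- fit_gene_anova(sub[1, ], sheet,
      model_spec(c("tissue", "case"), random = "case"),
      gene = members)
    an <- dplyr::select(fit$table, -"gene")
    an$term <- c("tissue", "patient")
    comp <- dplyr::select(
      dplyr::filter(fit$components, TRUE), -"gene")
    comp$component <- sub("^case$", "patient", comp$component)
  } else {
    m_s <- colMeans(sub)
    sfit <- fit_gene_anova(m_s, sheet,
      model_spec(c("tissue", "case"), random = "case"),
      gene = "sample_mean")
    st <- sfit$table
    sres <- sfit$residual
    df_t <- st$df[1]
    df_p <- st$df[2]
    df_s <- sres$df
    ss_t <- g * st$sumsq[1]
    ss_p <- g * st$sumsq[2]
    ss_s <- g * sres$sumsq
    gbar <- rowMeans(sub)
    ss_g <- n * sum((gbar - mean(gbar))^2)
    df_g <- g - 1
    ss_tot <- sum((sub - mean(sub))^2)
    ss_res <- max(ss_tot - ss_t - ss_p - ss_s - ss_g, 0)
    df_res <- (g - 1) * (n - 1)
    ms <- c(ss_t, ss_p, ss_g, ss_s) / c(df_t, df_p, df_g, df_s)
    ms_res <- ss_res / df_res

    # T, P tested against the sample stratum; G, S against the residual
    f_t <- ms[1] / ms[4]
    f_p <- ms[2] / ms[4]
    f_g <- ms[3] / ms_res
    f_s <- ms[4] / ms_res
    an <- tibble(
      term = c("tissue", "patient", "gene", "sample(tissue*patient)"),
      df = c(df_t, df_p, df_g, df_s),
      sumsq = c(ss_t, ss_p, ss_g, ss_s),
      meansq = ms,
      statistic = c(f_t, f_p, f_g, f_s),
      df_denom = c(df_s, df_s, df_res, df_res),
      p.value = pf(c(f_t, f_p, f_g, f_s), c(df_t, df_p, df_g, df_s),
        c(df_s, df_s, df_res, df_res), lower.tail = FALSE)
    )
    # method-of-moments components: each observation carries its sample's
    # effect g times per sample stratum df, genes n times
    sigma_e <- ms_res
    sigma_s <- (ms[4] - ms_res) / g
    sigma_g <- (ms[3] - ms_res) / n
    # patient component from the sample-level equating, where the
    # sample-level residual estimates sigma_s + sigma_e / g
    p_comp <- sfit$components$raw[sfit$components$component == "case"] / 1
    comp <- tibble(
      component = c("patient", "gene", "sample(tissue*patient)", "residual"),
      raw = c(p_comp, sigma_g, sigma_s, sigma_e),
      estimate = pmax(c(p_comp, sigma_g, sigma_s, sigma_e), 0)
    )
  }

  long <- tibble(
    gene = rep(members, n),
    tissue = rep(as.character(sheet$tissue), each = g),
    value = as.vector(sub)
  )
  gene_means <- long |>
    dplyr::group_by(.data$gene, .data$tissue) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )

  structure(
    list(
      set = set_name, n_genes = g, anova = an,
      components = comp, gene_means = gene_means
    ),
    class = "go_anova_record"
  )
}

#' @export
print.go_anova_record <- function(x, ...) {
  t_row <- x$anova[x$anova$term == "tissue", ]
  cat(sprintf(
    "<go_anova_record> '%s' (%d genes): tissue F = %.3f, p = %.3g\n",
    x$set, x$n_genes, t_row$statistic, t_row$p.value
  ))
  invisible(x)
}

#' @export
tidy.go_anova_record <- function(x, ...) {
  dplyr::mutate(x$anova, set = x$set, .before = 1)
}

#' Run GO-ANOVA over a whole collection
#'
#' @param mat,sheet As in [go_anova()].
#' @param sets A [gene_set_collection()].
#' @param min_size Minimum member count after intersection (default 2).
#' @return Tibble: set, size, statistic (tissue F), p.value, q.value (BH
#'   across sets).
#' @export
go_anova_table <- function(mat, sheet, sets, min_size = 2) {
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(sets[[nm]], rownames(mat))
    if (length(members) < min_size) return(NULL)
    rec <- go_anova(mat, sheet, members, set_name = nm)
    t_row <- rec$anova[rec$anova$term == "tissue", ]
    tibble(
      set = nm, size = rec$n_genes,
      statistic = t_row$statistic, p.value = t_row$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q.value <- bh_fdr_na(out$p.value)
  out
}

#' Overlap report for named collections of significant set (or gene) names
#'
#' Computes every region of the Venn partition of the input lists plus, for
#' each ordered pair, the shared count as a percentage of each list (rounded
#' to two decimals).
#'
#' @param lists Named list (>= 2) of character vectors.
#' @return A list of class `overlap_report`: `regions` (tibble: membership
#'   pattern, count), `pairs` (tibble: list_a, list_b, n_a, n_b, shared,
#'   pct_of_a, pct_of_b), `sizes`.
#' @export
setlist_overlap <- function(lists) {
  if (length(lists) < 2) fc_abort("need at least two lists")
  if (is.null(names(lists)) || any(names(lists) == "")) {
    fc_abort("lists must be named")
  }
  lists <- lapply(lists, function(x) unique(as.character(x)))
  all_ids <- unique(unlist(lists))
  memb <- vapply(lists, function(l) all_ids %in% l, logical(length(all_ids)))
  memb <- matrix(memb, nrow = length(all_ids),
    dimnames = list(NULL, names(lists)))
  pattern <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  pats <- table(pattern)
  regions <- tibble(
    region = names(pats),
    count = as.integer(pats)
  ) |> dplyr::arrange(dplyr::desc(.data$count))

  pair_idx <- combn(names(lists), 2, simplify = FALSE)
  pairs <- purrr::map_dfr(pair_idx, function(p) {
    shared <- length(intersect(lists[[p[1]]], lists[[p[2]]]))
    tibble(
      list_a = p[1], list_b = p[2],
      n_a = length(lists[[p[1]]]), n_b = length(lists[[p[2]]]),
      shared = shared,
      pct_of_a = round(100 * shared / length(lists[[p[1]]]), 2),
      pct_of_b = round(100 * shared / length(lists[[p[2]]]), 2)
    )
  })
  structure(
    list(regions = regions, pairs = pairs, sizes = lengths(lists)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d lists (sizes: %s)\n",
    length(x$sizes), paste(x$sizes, collapse = ", ")))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.overlap_report <- function(x, ...) x$pairs
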