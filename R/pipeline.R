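#' Pipeline configuration
#'
#' Validated bag of thresholds, stage toggles and file paths driving
#' [run_pipeline()]. Every threshold is range-checked up front so a bad
#' configuration fails before any stage runs.
#'
#' @param simulate If `TRUE` (default) the input dataset is generated by
#'   [simulate_dataset()] with `sim` parameters; otherwise `expr_path`,
#'   `sheet_path` (and optionally `controls_path`, `gmt_path`) are read.
#' @param sim A [sim_params()] object (used when `simulate = TRUE`).
#' @param expr_path,sheet_path,controls_path,gmt_path Input TSV/GMT paths.
#' @param alpha_detect Detection significance level in (0, 1).
#' @param fdr FDR level for gene lists, in (0, 1).
#' @param fold_change Fold-change cutoff for gene lists (>= 1).
#' @param cv_folds Outer/inner fold count (>= 2).
#' @param permutations GSEA phenotype permutations (>= 10).
#' @param feature_counts Candidate feature counts for nested CV.
#' @param min_set_size GSEA minimum set size.
#' @param outlier_sd PCA QC distance threshold.
#' @param stages Character vector of stages to run, a subset of
#'   `c("preprocess", "anova", "genesets", "cv", "concord")`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for the report bundle TSVs (`NULL` = do
#'   not write).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = sim_params(
                              n_genes = 2000, n_patients = 12, seed = 1
                            ),
                            expr_path = NULL, sheet_path = NULL,
                            controls_path = NULL, gmt_path = NULL,
                            alpha_detect = 0.05,
                            fdr = 0.05,
                            fold_change = 2,
                            cv_folds = 10,
                            permutations = 200,
                            feature_counts = c(50, 100, Inf),
                            min_set_size = 5,
                            outlier_sd = 4,
                            stages = c("preprocess", "anova", "genesets",
                              "cv", "concord"),
                            seed = 1L,
                            out_dir = NULL) {
  if (alpha_detect <= 0 || alpha_detect >= 1) {
    fc_abort("alpha_detect must be in (0, 1)")
  }
  if (fdr <= 0 || fdr >= 1) fc_abort("fdr must be in (0, 1)")
  if (fold_change < 1) fc_abort("fold_change cutoff must be >= 1")
  if (cv_folds < 2) fc_abort("cv_folds must be >= 2")
  if (permutations < 10) fc_abort("permutations must be >= 10")
  bad <- setdiff(stages, c("preprocess", "anova", "genesets", "cv", "concord"))
  if (length(bad)) fc_abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (!simulate && (is.null(expr_path) || is.null(sheet_path))) {
    fc_abort("expr_path and sheet_path are required when simulate = FALSE")
  }
  structure(
    list(
      simulate = simulate, sim = sim,
      expr_path = expr_path, sheet_path = sheet_path,
      controls_path = controls_path, gmt_path = gmt_path,
      alpha_detect = alpha_detect, fdr = fdr, fold_change = fold_change,
      cv_folds = cv_folds, permutations = permutations,
      feature_counts = feature_counts, min_set_size = min_set_size,
      outlier_sd = outlier_sd, stages = stages,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `sim:` may hold a nested
#' map of [sim_params()] arguments. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    fc_abort(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  }
  raw$sim <- do.call(sim_params, sim_args)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    fc_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  pipeline_log("stage %s done in %.1fs", name,
    as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the full FF/FFPE concordance pipeline
#'
#' Chains the stages on simulated or on-disk inputs: detection calls and
#' normalization with PCA QC; combined mixed-model ANOVA (tissue + storage +
#' case + tissue:storage, case random) and per-storage ANOVA (tissue + batch
#' + block age, batch random); FDR/fold-change gene lists; GO-enrichment,
#' GSEA and GO-ANOVA with set-list overlaps; nested cross-validated
#' FF-vs-FFPE classification; and gene-list concordance reporting. When
#' `config$out_dir` is set, every result table is written as TSV.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: a named list of result tibbles plus
#'   a `summary` tibble of headline numbers.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    fc_abort("config must be a pipeline_config")
  }
  bundle <- list()

  dat <- run_stage("input", {
    if (config$simulate) {
      sim <- simulate_dataset(config$sim)
      sim$sets <- simulate_gene_sets(config$sim)
      sim
    } else {
      list(
        expr = read_expression_matrix(config$expr_path),
        sheet = read_sample_sheet(config$sheet_path),
        controls = if (!is.null(config$controls_path)) {
          read_expression_matrix(config$controls_path)
        },
        sets = if (!is.null(config$gmt_path)) read_gmt(config$gmt_path),
        probes = NULL, probe_map = NULL
      )
    }
  })
  expr <- dat$expr
  sheet <- dat$sheet

  if ("preprocess" %in% config$stages) {
    pre <- run_stage("preprocess", {
      det <- if (!is.null(dat$controls)) {
        detection_calls(expr, dat$controls,
          alpha = config$alpha_detect,
          probes = dat$probes, probe_map = dat$probe_map
        )
      }
      preq <- if ("delta_ct" %in% names(sheet)) {
        suppressWarnings(prequalify(sheet$delta_ct, sample = sheet$sample))
      }
      # normalization on the raw scale, then back to log2 with a floor at 1
      norm <- log2(pmax(quantile_normalize(2^expr), 1))
      counts <- if (!is.null(det)) {
        setNames(det$counts$n_detected, det$counts$sample)
      }
      qc <- pca_qc(norm,
        outlier_sd = config$outlier_sd,
        detected_counts = counts,
        min_detected = if (!is.null(counts)) {
          round(0.25 * nrow(expr))
        }
      )
      list(det = det, preq = preq, norm = norm, qc = qc)
    })
    keep <- !pre$qc$scores$outlier
    if (any(!keep)) {
      pipeline_log("excluding %d QC outlier sample(s)", sum(!keep))
    }
    expr <- pre$norm[, keep, drop = FALSE]
    sheet <- sheet[keep, , drop = FALSE]
    sheet <- droplevels(sheet)
    bundle$detection <- if (!is.null(pre$det)) pre$det$counts
    bundle$prequal <- pre$preq
    bundle$qc <- pre$qc$scores
  }

  lists <- list()
  if ("anova" %in% config$stages) {
    an <- run_stage("anova", {
      fit <- genomewide_anova(expr, sheet, spec_combined())
      tidy_fit <- tidy(fit)
      storage_list <- select_differential(
        fit, "storage", config$fdr, config$fold_change
      )
      tumor_list <- select_differential(
        fit, "tissue", config$fdr, config$fold_change
      )
      inter_list <- select_differential(
        fit, "tissue:storage", config$fdr, 1,
        fc_term = "tissue"
      )
      per_storage <- lapply(levels(sheet$storage), function(st) {
        idx <- sheet$storage == st
        sub_sheet <- droplevels(sheet[idx, , drop = FALSE])
        fit_s <- genomewide_anova(
          expr[, idx, drop = FALSE], sub_sheet,
          if (all(c("batch", "block_age") %in% names(sub_sheet)) &&
            nlevels(sub_sheet$batch) > 1) {
            spec_within_storage()
          } else {
            model_spec(c("tissue", "case"), random = "case")
          }
        )
        select_differential(fit_s, "tissue", config$fdr, config$fold_change)
      })
      names(per_storage) <- paste0("tumor_", levels(sheet$storage))
      list(
        fit = fit, tidy = tidy_fit,
        storage_list = storage_list, tumor_list = tumor_list,
        inter_list = inter_list, per_storage = per_storage
      )
    })
    lists <- c(
      list(
        storage = an$storage_list$gene,
        tumor_combined = an$tumor_list$gene
      ),
      lapply(an$per_storage, function(l) l$gene)
    )
    bundle$anova <- an$tidy
    bundle$mean_f <- mean_f_ratio(an$fit)
    bundle$variance_partition <- variance_partition(an$fit)
    bundle$gene_lists <- dplyr::bind_rows(
      c(
        list(
          storage = an$storage_list, tumor_combined = an$tumor_list,
          interaction = an$inter_list
        ),
        an$per_storage
      ),
      .id = "list"
    )
  }

  if ("genesets" %in% config$stages && !is.null(dat$sets)) {
    gs <- run_stage("genesets", {
      enr <- if (length(lists)) {
        go_enrichment(lists$tumor_combined, rownames(expr), dat$sets)
      }
      per_storage_sets <- lapply(levels(sheet$storage), function(st) {
        idx <- sheet$storage == st
        gsea_tab <- gsea(
          expr[, idx, drop = FALSE], sheet$tissue[idx], dat$sets,
          n_permutations = config$permutations,
          seed = config$seed, min_size = config$min_set_size
        )
        goa <- go_anova_table(
          expr[, idx, drop = FALSE],
          droplevels(sheet[idx, , drop = FALSE]), dat$sets
        )
        list(gsea = gsea_tab, goa = goa)
      })
      names(per_storage_sets) <- levels(sheet$storage)
      list(enr = enr, per_storage = per_storage_sets)
    })
    set_lists <- unlist(lapply(names(gs$per_storage), function(st) {
      x <- gs$per_storage[[st]]
      out <- list(
        x$gsea$set[!is.na(x$gsea$p.value) & x$gsea$p.value < 0.05],
        x$goa$set[!is.na(x$goa$q.value) & x$goa$q.value <= config$fdr]
      )
      names(out) <- paste0(c("gsea_", "goanova_"), st)
      out
    }), recursive = FALSE)
    bundle$enrichment <- gs$enr
    bundle$gsea <- dplyr::bind_rows(
      lapply(gs$per_storage, function(x) x$gsea), .id = "storage"
    )
    bundle$go_anova <- dplyr::bind_rows(
      lapply(gs$per_storage, function(x) x$goa), .id = "storage"
    )
    if (sum(lengths(set_lists) > 0) >= 2) {
      nonempty <- set_lists[lengths(set_lists) > 0]
      so <- setlist_overlap(nonempty)
      bundle$set_overlap <- so$pairs
    }
  }

  if ("cv" %in% config$stages && "storage" %in% names(sheet) &&
    nlevels(sheet$storage) == 2) {
    cvres <- run_stage("cv", {
      cross_validate(
        expr, sheet, "storage",
        cv_spec(
          classifier = "knn1",
          outer_folds = min(config$cv_folds, ncol(expr)),
          inner_folds = min(config$cv_folds, ncol(expr) - 2),
          feature_counts = config$feature_counts,
          seed = config$seed
        )
      )
    })
    bundle$cv <- glance(cvres)
    bundle$cv_folds <- cvres$folds
  }

  if ("concord" %in% config$stages && length(lists) >= 2) {
    conc <- run_stage("concord", {
      gene_lists <- lists[intersect(
        c("tumor_FF", "tumor_FFPE", "tumor_combined"), names(lists)
      )]
      if (length(gene_lists) >= 2) list_overlap(gene_lists)
    })
    if (!is.null(conc)) {
      bundle$concordance <- conc$pairs
      bundle$venn_regions <- conc$regions
    }
  }

  bundle$summary <- pipeline_summary(bundle)
  if (!is.null(config$out_dir)) {
    write_report_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

pipeline_summary <- function(bundle) {
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1]] <<- tibble(metric = metric, value = value)
  }
  if (!is.null(bundle$detection)) {
    add("mean_detected_share_pct", round(mean(bundle$detection$share_pct), 2))
  }
  if (!is.null(bundle$qc)) add("n_qc_outliers", sum(bundle$qc$outlier))
  if (!is.null(bundle$gene_lists)) {
    for (l in unique(bundle$gene_lists$list)) {
      add(paste0("n_genes_", l), sum(bundle$gene_lists$list == l))
    }
  }
  if (!is.null(bundle$cv)) add("cv_accuracy_pct", bundle$cv$accuracy_pct)
  if (!is.null(bundle$concordance)) {
    for (i in seq_len(nrow(bundle$concordance))) {
      p <- bundle$concordance[i, ]
      add(paste0("overlap_", p$list_a, "_", p$list_b, "_pct_of_a"), p$pct_of_a)
    }
  }
  dplyr::bind_rows(rows)
}

write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x)) {
      readr::write_tsv(x, file.path(dir, paste0(nm, ".tsv")))
    }
  }
  invisible(dir)
}
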