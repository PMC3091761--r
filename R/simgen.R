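#' Simulation parameters for a paired FF/FFPE expression study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' whole-genome bead-array study of paired breast tumor/normal tissue profiled
#' from both fresh-frozen (FF) and formalin-fixed paraffin-embedded (FFPE)
#' blocks: 18,391 genes, 18 patients with all four samples
#' (tumor/normal x FF/FFPE) of a patient on one 8-sample chip and three chips
#' per processing batch.
#'
#' Expression is generated additively on the log2 scale:
#' gene baseline + tissue effect + storage effect + tissue:storage interaction
#' + per-patient random effect + per-batch random effect + block-age trend
#' (FFPE samples only) + i.i.d. noise. A configurable fraction of genes
#' receives tissue/storage/interaction effects of magnitude
#' `effect_size_log2` with random Rademacher signs, so up- and down-regulated
#' lists are both populated.
#'
#' @param n_genes Number of genes on the array.
#' @param n_patients Number of patients; each contributes 4 samples.
#' @param samples_per_chip Chip capacity (the 4 samples of a patient always
#'   share a chip).
#' @param chips_per_batch Chips processed together in one batch.
#' @param n_probes_per_gene Probe replicates per gene, used by detection calls.
#' @param n_negative_controls Negative-control probes per sample.
#' @param baseline_mean,baseline_sd Gene baseline distribution (log2 units).
#' @param noise_sd Residual SD (log2 units).
#' @param probe_sd Probe-replicate SD around the gene value (log2 units).
#' @param person_sd,batch_sd Random-effect SDs (log2 units).
#' @param control_mean,control_sd Negative-control background (log2 units).
#' @param frac_tissue_de,frac_storage_de,frac_interaction Fractions of genes
#'   with a true tissue, storage, or interaction effect.
#' @param effect_size_log2 Magnitude of injected effects (1.0 = 2-fold).
#' @param block_age_slope log2 units per year of block age, applied to FFPE
#'   samples only.
#' @param block_age_range Years; block ages drawn uniformly from the integer
#'   range.
#' @param delta_ct_mean,delta_ct_sd qPCR prequalification delta-Ct
#'   distribution (cycles).
#' @param frac_high_delta_ct Fraction of samples forced to a delta-Ct just
#'   above the 12-cycle prequalification limit (in (12, 12.5]).
#' @param n_gene_sets,set_size_range GO-style gene-set geometry.
#' @param frac_coordinated_sets Fraction of sets whose members share a common
#'   injected tissue effect (set-level signal for GSEA/GO-ANOVA tests).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_genes = 200, n_patients = 6, seed = 1)
#' sim <- simulate_dataset(p)
#' dim(sim$expr)
sim_params <- function(n_genes = 18391L,
                       n_patients = 18L,
                       samples_per_chip = 8L,
                       chips_per_batch = 3L,
                       n_probes_per_gene = 3L,
                       n_negative_controls = 500L,
                       baseline_mean = 10,
                       baseline_sd = 2,
                       noise_sd = 0.5,
                       probe_sd = 0.25,
                       person_sd = 0.5,
                       batch_sd = 0.3,
                       control_mean = 9,
                       control_sd = 1,
                       frac_tissue_de = 0.10,
                       frac_storage_de = 0.10,
                       frac_interaction = 0.05,
                       effect_size_log2 = 1.0,
                       block_age_slope = 0.1,
                       block_age_range = c(3L, 6L),
                       delta_ct_mean = 8.3,
                       delta_ct_sd = 1.5,
                       frac_high_delta_ct = 4 / 72,
                       n_gene_sets = 50L,
                       set_size_range = c(10L, 50L),
                       frac_coordinated_sets = 0.2,
                       seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
    samples_per_chip = as.integer(samples_per_chip),
    chips_per_batch = as.integer(chips_per_batch),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    n_negative_controls = as.integer(n_negative_controls),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, probe_sd = probe_sd,
    person_sd = person_sd, batch_sd = batch_sd,
    control_mean = control_mean, control_sd = control_sd,
    frac_tissue_de = frac_tissue_de, frac_storage_de = frac_storage_de,
    frac_interaction = frac_interaction,
    effect_size_log2 = effect_size_log2,
    block_age_slope = block_age_slope,
    block_age_range = as.integer(block_age_range),
    delta_ct_mean = delta_ct_mean, delta_ct_sd = delta_ct_sd,
    frac_high_delta_ct = frac_high_delta_ct,
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    frac_coordinated_sets = frac_coordinated_sets,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fracs <- c(
    p$frac_tissue_de, p$frac_storage_de, p$frac_interaction,
    p$frac_coordinated_sets, p$frac_high_delta_ct
  )
  if (any(fracs < 0 | fracs > 1)) {
    fc_abort("all effect/fraction parameters must lie in [0, 1]")
  }
  sds <- c(
    p$baseline_sd, p$noise_sd, p$probe_sd, p$person_sd, p$batch_sd,
    p$control_sd, p$delta_ct_sd
  )
  if (any(sds < 0)) fc_abort("all SD parameters must be >= 0")
  if (p$n_probes_per_gene < 1L) fc_abort("n_probes_per_gene must be >= 1")
  if (p$n_patients < 2L) {
    fc_abort("n_patients must be >= 2 (no random-effect variance estimable)")
  }
  if (p$samples_per_chip < 4L || p$samples_per_chip %% 4L != 0L) {
    fc_abort("samples_per_chip must be a positive multiple of 4")
  }
  if (any(p$set_size_range > p$n_genes)) {
    fc_abort("gene-set sizes cannot exceed n_genes")
  }
  if (diff(p$set_size_range) < 0) fc_abort("set_size_range must be increasing")
  invisible(p)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# sample sheet layout implied by the study design: the four samples of each
# patient share a chip; chips fill with patients in order; batches group chips
sim_sample_sheet <- function(p) {
  patients_per_chip <- p$samples_per_chip %/% 4L
  patient <- sprintf("p%02d", seq_len(p$n_patients))
  sheet <- tidyr::expand_grid(
    case = patient,
    tissue = factor(c("normal", "tumor"), levels = c("normal", "tumor")),
    storage = factor(c("FF", "FFPE"), levels = c("FF", "FFPE"))
  )
  sheet <- dplyr::mutate(sheet,
    case = factor(.data$case, levels = patient),
    sample = paste(.data$case, .data$tissue, .data$storage, sep = "_"),
    chip = sprintf("chip%02d", (as.integer(.data$case) - 1L) %/%
      patients_per_chip + 1L)
  )
  chip_no <- as.integer(factor(sheet$chip, levels = unique(sheet$chip)))
  sheet$batch <- factor(sprintf(
    "batch%02d",
    (chip_no - 1L) %/% p$chips_per_batch + 1L
  ))
  sheet$chip <- factor(sheet$chip)
  dplyr::select(
    sheet, "sample", "case", "tissue", "storage", "chip", "batch"
  )
}

#' Simulate a paired FF/FFPE tumor/normal expression dataset
#'
#' Draws a full synthetic study under the additive log2-scale model the
#' downstream mixed-model ANOVA assumes (see [sim_params()]), including
#' probe-level replicates, negative-control probes, delta-Ct prequalification
#' values and a ground-truth table of injected effects. Genes belonging to
#' "coordinated" gene sets (see [simulate_gene_sets()]) receive an additional
#' shared tissue effect, so set-level tests have true signal to recover.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements:
#' \describe{
#'   \item{expr}{n_genes x n_samples matrix of log2 intensities (probe means).}
#'   \item{probes}{(n_genes * n_probes) x n_samples matrix of probe-level
#'     log2 intensities, rownames `<gene>_probe<k>`.}
#'   \item{probe_map}{character vector mapping probe rows to gene ids.}
#'   \item{sheet}{tibble sample sheet: sample, case, tissue, storage, chip,
#'     batch, block_age, delta_ct.}
#'   \item{controls}{n_negative_controls x n_samples matrix of log2
#'     negative-control intensities.}
#'   \item{truth}{tibble: gene, tissue_effect, storage_effect,
#'     interaction_effect (log2 units; zero outside the DE fractions;
#'     coordinated set contributions included).}
#'   \item{set_truth}{tibble: set, coordinated, set_effect.}
#'   \item{params}{the input parameters.}
#' }
#' @export
simulate_dataset <- function(params) {
  p <- validate_sim_params(params)
  genes <- gene_ids(p$n_genes)
  sheet <- sim_sample_sheet(p)
  n_samp <- nrow(sheet)

  membership <- sim_set_membership(p) # seeded independently of the data draw

  set.seed(child_seed(p$seed, "data"))
  baseline <- rnorm(p$n_genes, p$baseline_mean, p$baseline_sd)

  draw_effect <- function(frac) {
    hit <- runif(p$n_genes) < frac
    eff <- numeric(p$n_genes)
    eff[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) * p$effect_size_log2
    eff
  }
  tissue_eff <- draw_effect(p$frac_tissue_de)
  storage_eff <- draw_effect(p$frac_storage_de)
  inter_eff <- draw_effect(p$frac_interaction)

  # coordinated sets add a shared tissue effect to every member
  for (i in seq_along(membership$sets)) {
    if (membership$coordinated[i]) {
      idx <- match(membership$sets[[i]], genes)
      tissue_eff[idx] <- tissue_eff[idx] + membership$set_effect[i]
    }
  }

  person_re <- matrix(
    rnorm(p$n_genes * p$n_patients, 0, p$person_sd),
    p$n_genes, p$n_patients
  )
  n_batches <- nlevels(sheet$batch)
  batch_re <- matrix(
    rnorm(p$n_genes * n_batches, 0, p$batch_sd),
    p$n_genes, n_batches
  )

  ages <- sample(
    seq(p$block_age_range[1], p$block_age_range[2]),
    p$n_patients,
    replace = TRUE
  )
  sheet$block_age <- ages[as.integer(sheet$case)]

  is_tumor <- as.numeric(sheet$tissue == "tumor")
  is_ffpe <- as.numeric(sheet$storage == "FFPE")
  mean_age <- mean(seq(p$block_age_range[1], p$block_age_range[2]))

  expr <- matrix(0, p$n_genes, n_samp, dimnames = list(genes, sheet$sample))
  for (s in seq_len(n_samp)) {
    expr[, s] <- baseline +
      tissue_eff * is_tumor[s] +
      storage_eff * is_ffpe[s] +
      inter_eff * is_tumor[s] * is_ffpe[s] +
      person_re[, as.integer(sheet$case[s])] +
      batch_re[, as.integer(sheet$batch[s])] +
      p$block_age_slope * (sheet$block_age[s] - mean_age) * is_ffpe[s]
  }
  expr <- expr + matrix(rnorm(length(expr), 0, p$noise_sd), nrow(expr))

  set.seed(child_seed(p$seed, "probes"))
  np <- p$n_probes_per_gene
  probe_map <- rep(genes, each = np)
  probes <- expr[probe_map, , drop = FALSE] +
    matrix(rnorm(p$n_genes * np * n_samp, 0, p$probe_sd), p$n_genes * np)
  rownames(probes) <- paste0(probe_map, "_probe", rep(seq_len(np), p$n_genes))
  # the analysis matrix is the probe mean
  expr_mean <- rowsum(probes, probe_map)[genes, , drop = FALSE] / np

  set.seed(child_seed(p$seed, "controls"))
  controls <- matrix(
    rnorm(p$n_negative_controls * n_samp, p$control_mean, p$control_sd),
    p$n_negative_controls, n_samp,
    dimnames = list(sprintf("neg%04d", seq_len(p$n_negative_controls)),
      sheet$sample)
  )

  set.seed(child_seed(p$seed, "delta_ct"))
  dct <- rnorm(n_samp, p$delta_ct_mean, p$delta_ct_sd)
  n_high <- round(p$frac_high_delta_ct * n_samp)
  if (n_high > 0) {
    hi <- sample(n_samp, n_high)
    dct[hi] <- runif(n_high, 12 + 1e-3, 12.5)
  }
  sheet$delta_ct <- round(pmax(dct, 0), 2)

  truth <- tibble(
    gene = genes,
    tissue_effect = tissue_eff,
    storage_effect = storage_eff,
    interaction_effect = inter_eff
  )
  set_truth <- tibble(
    set = membership$names,
    coordinated = membership$coordinated,
    set_effect = membership$set_effect
  )

  list(
    expr = expr_mean, probes = probes, probe_map = probe_map,
    sheet = sheet, controls = controls, truth = truth,
    set_truth = set_truth, params = p
  )
}

# gene-set membership and coordination flags are drawn from a child seed of
# their own so simulate_gene_sets() and simulate_dataset() stay consistent
sim_set_membership <- function(p) {
  genes <- gene_ids(p$n_genes)
  set.seed(child_seed(p$seed, "genesets"))
  size_choices <- seq(p$set_size_range[1], p$set_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), p$n_gene_sets,
    replace = TRUE)]
  sets <- lapply(sizes, function(k) sort(sample(genes, k)))
  names <- sprintf("SET%03d", seq_len(p$n_gene_sets))
  coordinated <- runif(p$n_gene_sets) < p$frac_coordinated_sets
  set_effect <- ifelse(
    coordinated,
    sample(c(-1, 1), p$n_gene_sets, replace = TRUE) * p$effect_size_log2,
    0
  )
  list(
    names = names, sets = sets, sizes = sizes,
    coordinated = coordinated, set_effect = set_effect
  )
}

#' Simulate GO-style gene sets
#'
#' Draws `n_gene_sets` gene sets without replacement within each set, with a
#' configurable fraction flagged "coordinated" (their members share a common
#' injected tissue effect in [simulate_dataset()] under the same seed).
#'
#' @param params A [sim_params()] object.
#' @return A `gene_set_collection` (see [read_gmt()]) whose element metadata
#'   carries the coordinated flag in the description field.
#' @export
simulate_gene_sets <- function(params) {
  p <- validate_sim_params(params)
  if (p$n_gene_sets < 1L) fc_abort("n_gene_sets must be >= 1")
  m <- sim_set_membership(p)
  gene_set_collection(
    sets = setNames(m$sets, m$names),
    description = ifelse(m$coordinated, "coordinated", "background")
  )
}

#' Write all simulated artifacts to a directory as TSV/GMT
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expr = file.path(dir, "expression.tsv"),
    probes = file.path(dir, "probes.tsv"),
    sheet = file.path(dir, "sample_sheet.tsv"),
    controls = file.path(dir, "negative_controls.tsv"),
    truth = file.path(dir, "truth.tsv"),
    sets = file.path(dir, "gene_sets.gmt")
  )
  write_expression_matrix(sim$expr, paths["expr"])
  write_expression_matrix(sim$probes, paths["probes"], id_col = "probe")
  readr::write_tsv(sim$sheet, paths["sheet"])
  write_expression_matrix(sim$controls, paths["controls"], id_col = "control")
  readr::write_tsv(sim$truth, paths["truth"])
  write_gmt(simulate_gene_sets(sim$params), paths["sets"])
  invisible(paths)
}
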