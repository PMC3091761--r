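---
title: "Methods: mixed-model ANOVA and concordance analysis for paired FF/FFPE expression studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model ANOVA and concordance analysis for paired FF/FFPE expression studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ffpeconcord)
```

# The problem

Paired preservation studies profile the same patients four ways — tumor and
adjacent normal tissue, each from fresh-frozen (FF) and formalin-fixed
paraffin-embedded (FFPE) blocks — to ask whether archival FFPE material can
stand in for frozen tissue. Statistically this is a small, heavily
structured design: a handful of patients, four correlated samples per
patient, chip and batch effects aligned with patients by construction, and
tens of thousands of genes. `ffpeconcord` implements the full analysis chain
for that design. This vignette records the models, the estimators, and every
place where a design decision had to be made.

# Models

## Per-gene mixed ANOVA

The combined analysis fits, per gene, the log2 intensity

$$y = \mu + \text{Tissue} + \text{Storage} + \text{CaseID}
      + \text{Tissue}\times\text{Storage} + \varepsilon,$$

with tissue (tumor/normal) and storage (FFPE/FF) fixed — their levels are
all conditions of interest — and the patient (case ID) random, since
patients are a sample from a population. The errors are assumed independent
normal with common variance. When FF and FFPE samples are analyzed
separately, the model is

$$y = \mu + \text{Tissue} + \text{Batch} + \text{BlockAge} + \varepsilon,$$

batch random and block age a linear covariate (one degree of freedom).
Because all four samples of a patient share one chip, batch and case are
aliased; the two factors are never entered together. `model_spec()` builds
either form (convenience constructors `spec_combined()` and
`spec_within_storage()`), and arbitrary term lists with declared
random/covariate roles are accepted.

## Estimation

Sums of squares are **sequential (Type I)** in the declared term order,
computed through successive orthogonal-projection differences; this is the
decomposition on which method-of-moments equating is defined. For every
random term the **expected mean squares** are computed numerically from the
realized design via quadratic-form traces,
$c_{t,r} = \operatorname{tr}(Q_t Z_r Z_r^\top)/\mathrm{df}_t$, rather than
from balanced-case formulas, so the estimator is exact after a QC outlier is
excluded. Equating the observed mean squares of the random terms and the
residual to their expectations gives the variance components; negative
solutions are truncated at zero with the raw value retained in the record
(standard MoM practice).

Each term's F statistic uses the **EMS-implied denominator**: the residual
mean square when no random component enters the term's null expectation,
otherwise a linear combination of mean squares synthesized from the EMS
system, with Satterthwaite degrees of freedom. On the balanced paired design
the case term's denominator is the residual and the fixed-term denominators
collapse to the residual mean square; the general machinery only matters
off-balance.

LS-means are computed on a balanced reference grid over all categorical
factors (covariates at their observed mean) from the minimum-norm OLS fit;
fold changes between the two levels of each fixed factor use the
signed-reciprocal convention $2^d$ for $d \ge 0$ and $-2^{-d}$ otherwise, so
"−2" reads as 2-fold down.

## Percent of variance per term

The study-style report "x% of the variation was contributed by storage"
assigns a variance share to *fixed* terms too. We follow the genomic-suite
convention and solve the full method-of-moments system with **every** model
term treated as a component (fixed-term rows are their sequential mean
squares; the covariate's kernel is normalized by its variance so its
component is the variance it contributes to $y$), truncate negatives at
zero, and normalize to 100% per gene. For the declared random terms this
coincides with the proper MoM components on balanced designs. A
zero-variance gene is 100% residual by convention. These shares are
descriptive; hypothesis tests always use the EMS-based F above.

## Set-level models

*GO-enrichment* compares "significant genes in a category / all significant
genes" with "genes on the chip in that category / all genes on the chip" by
a 1-df chi-square on the 2×2 table (list vs whole chip), without continuity
correction — the expected counts are large in the genome-wide regime, and a
warning (not a Fisher fallback) is raised when one drops below 5. The
enrichment score is $-\log p$, natural log by default and base-10 by option,
used only to rank functional groups.

*GSEA* ranks genes by the signal-to-noise ratio
$(\bar{x}_1-\bar{x}_0)/(s_1+s_0)$ with each class SD floored at
$0.2\,|\bar{x}|$ (0.2 if the mean is zero), and walks the ranked list with
hit increments proportional to $|r|^{p}$ (default $p=1$; $p=0$ gives the
unweighted Kolmogorov–Smirnov form) and miss decrements $1/(N-|S|)$. The ES
is the running sum's extremum of maximal magnitude; near-ties, including
the exact $+x/-x$ tie, resolve to the earliest position. Significance and
the NES come from **phenotype permutation** (the original default; gene
permutation destroys the correlation structure), normalizing by the mean
|permuted ES| of matching sign. Which phenotype is "positive" — and hence
the NES sign convention — is an explicit argument, not a guess.

*GO-ANOVA* stacks the member genes of one set and fits
$y = \mu + T + P + G + S(T{*}P) + \varepsilon$, the sample effect random and
nested in tissue × patient. The set-level result is the $T$ test against the
sample-stratum mean square. The implementation exploits the complete gene ×
sample crossing: sample-stratum terms are estimated on per-sample means of
the member genes and rescaled, which is algebraically exact for this
balanced stacking and keeps the cost linear in set size. A singleton set is
fitted without the $G$ and $S$ terms (they would be saturated) and then
reduces exactly to the per-gene paired model — a property the tests assert.

## Classification

Nested (two-level) cross-validation: stratified, seeded outer folds estimate
accuracy; within each outer training set an inner cross-validation picks the
feature count (and the LDA shrinkage intensity) with the best inner
accuracy, ties resolving to the smaller feature count. Feature ranking — by
the selected ANOVA term's p-value on the training subset, ties broken by
larger |fold change| then gene id — is always refit inside the training
fold, and a guard errors outright if a held-out sample id reaches the
ranking function. Classifiers: 1-nearest-neighbour (Euclidean; exact
distance ties go to the smallest training index, for determinism),
nearest centroid with equal priors, and linear discriminant analysis with
the pooled covariance blended toward its diagonal
($\Sigma_\lambda = (1-\lambda)\hat\Sigma + \lambda\,\mathrm{diag}\hat\Sigma$)
because $p \gg n$ makes the classical pooled covariance singular.
Percentages are reported to two decimals alongside raw correct/total counts;
the counts are the primary record, since percentages depend on rounding
conventions.

# The synthetic-data generator

`simulate_dataset()` draws data from exactly the additive log2-scale model
the ANOVA assumes: gene baseline $\sim N(10, 2^2)$; tissue, storage and
interaction effects of magnitude `effect_size_log2` (default 1 = 2-fold)
injected into configurable fractions of genes with Rademacher signs, so up-
and down-regulated lists are both populated; per-gene patient and batch
random effects; a block-age trend applied to FFPE samples only (fixation-
dependent degradation is the rationale for making age an FFPE-side effect);
probe replicates as gene value plus probe noise (the analysis matrix is the
probe mean, the replicates feed only detection calls); negative controls
$\sim N(9, 1)$; and i.i.d. noise. Layout follows the study design: the four
samples of a patient share one chip, chips fill in patient order, three
chips form a batch. ΔCt values are drawn around 8.3 cycles with a small
configurable fraction forced just above the 12-cycle prequalification limit
(but ≤ 12.5) to exercise the borderline path. Block ages are integer years
in 3–6.

Defaults the study does not pin down were chosen once as plausible values
and not revisited: noise SD 0.5 (matching the σ = 0.5 used in the power
arithmetic), person SD 0.5, batch SD 0.3, probe SD 0.25, controls at
$N(9,1)$ — which, against the $N(10,4)$ baseline spread, puts the simulated
per-sample detection share near the ~60% a successful bead-array run shows.
Gene sets are sampled without replacement within a set; a configurable
fraction is "coordinated", its members sharing a common tissue effect that
is recorded in the truth tables, giving GSEA and GO-ANOVA true set-level
signal to recover. Set membership derives from its own child seed, so
`simulate_gene_sets()` and `simulate_dataset()` agree without one calling
the other.

What the generator does **not** emulate: probe sequence effects,
hybridization chemistry, intensity-dependent (mean–variance) noise,
RNA-degradation kinetics, correlated gene–gene noise beyond the shared
random effects, and spatial array artifacts. Passing tests therefore
demonstrate correctness of the estimators under the assumed additive model
and calibrated behaviour under its null — not robustness to every failure
mode of real arrays.

# Numerical choices and conventions

* **Detection test**: with probe replicates, a one-sided Welch t-test of the
  gene's probes against the sample's negative controls; without, a one-sided
  z-score against the controls' mean/SD. The bead-array software's internal
  definition is not published; this choice is documented, not inferred.
* **Normalization order**: quantile normalization on the raw intensity
  scale, then log2 with a floor at 1.0 (the scanner-software order);
  configurable by normalizing outside `run_pipeline()`.
* **Quantile ties** receive the mean of the corresponding reference values
  (`limma::normalizeQuantiles(ties = TRUE)`).
* **FDR**: Benjamini–Hochberg step-up (`stats::p.adjust`), the standard
  reading of "FDR" in microarray practice; q-values are monotone in p and
  capped at 1.
* **PCA QC**: components of the gene-standardized matrix; a sample is an
  outlier when its standardized distance over the top 3 components exceeds
  4 SDs (only gross failures are flagged; the threshold is a parameter) or
  its detected-gene count falls below a configurable floor.
* **Sources-of-variation summary**: the conventional mean of per-gene F
  statistics per term (non-finite F excluded with a count). A literal
  "ratio of two F statistics" reading of that summary exists but is not
  used.
* **Degenerate inputs**: constant genes get all-zero sums of squares, zero
  components and a 100%-residual partition; unestimable terms (0 df) are
  flagged per term without failing the gene; saturated designs error.
* **Determinism**: one integer seed; all sub-generators (data, gene sets,
  probes, controls, ΔCt, folds, permutations) derive fixed child seeds from
  it, so equal seeds give byte-identical outputs end to end.

# Problem sizes

The test suite and the acceptance script run the estimators at reduced but
structurally faithful sizes chosen by us as sufficient for their purpose:
simulated studies of 150–2,000 genes and 6–18 patients for pipeline and
power properties, 50 patients for variance-component recovery (60–100 seeds),
2,000-gene null panels (40–60 seeds) for FDR control, exhaustive running-sum
oracles on all small ranked lists, 200 phenotype permutations for GSEA
calibration, and a 40-sample separable fixture for the classifiers. The
defaults of `sim_params()` remain at full study scale (18,391 genes,
18 patients).

# Known limitations

* Sequential (Type I) equating makes the reported per-term shares depend on
  the declared term order; the canonical orders follow the two model
  statements above. In unbalanced designs, fixed terms fitted after a random
  term can leak a small noncentrality into that term's expected mean square —
  inherent to Type I MoM; REML would avoid it but is deliberately out of
  scope.
* The LS-mean reference grid averages over random-factor levels observed in
  the data; with severe imbalance those LS-means are model extrapolations.
* GO structure is flat: sets are GMT entries with a category label; no DAG
  traversal or ancestor propagation, and no correction for overlap between
  sets beyond BH across set p-values.
* Permutation p-values are granular at 1/(number of same-sign permutations);
  `p = 0` means "beyond all permutations", not impossibility.
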