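Package: ffpeconcord
Title: Concordance Analysis of Paired Fresh-Frozen and FFPE Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for paired tumor/normal expression studies that
    compare fresh-frozen (FF) with formalin-fixed paraffin-embedded (FFPE)
    preservation. Provides detection calls against negative-control probes,
    quantile normalization, per-gene mixed-model ANOVA with method-of-moments
    variance components, FDR/fold-change gene-list selection, GO-enrichment
    chi-square scoring, gene set enrichment analysis (GSEA), set-level
    GO-ANOVA, nested cross-validated classification, and gene-list concordance
    reporting, together with a synthetic-data generator that emulates the
    paired chip/batch design so every stage is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    limma,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
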