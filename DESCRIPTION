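Package: coexlink
Title: Differential Coexpression Links as Survival Markers via Sample-Wise
    Product Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies conditional transcriptional relationships (gene pairs
    whose coexpression changes between normal and tumor tissue) and screens
    them for prognostic value. Pearson correlations are decomposed into
    per-sample products of z-scored expression values (the CILP statistic),
    turning differential coexpression testing into ordinary paired t-tests or
    linear regression with expression covariates. Significant links are
    dichotomized by their median product correlation across a tumor cohort
    and tested against overall survival with the log-rank test. Also provides
    global correlation-landscape diagnostics (strengthened/weakened pair
    partition, cross-condition regression slope, asymmetric correlation
    heatmaps), fold-based reproducibility assessment, preranked gene-set
    enrichment of differentially coexpressed genes, and a synthetic cohort
    generator with planted coexpression, expression, and hazard effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
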