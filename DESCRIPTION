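Package: AgingAccel
Title: Accelerated-Aging Network Analysis of Late-Onset Parkinson's Disease
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for studying accelerated aging in late-onset
    Parkinson's disease (LOPD) from bulk gene-expression cohorts. Provides
    correlation-ranked cosine k-nearest-neighbour predictors of age class and
    disease status (including an improved disease predictor that removes
    covariation captured by the principal components of healthy young
    samples), a transcriptomic aging score regressed on sigmoid-transformed
    chronological age, an aging-acceleration network built from differential
    Pearson and first-order partial correlations between patient and control
    groups, shortest-path analysis between aging and disease markers with a
    permutation null on path betweenness, and per-path hypergeometric
    gene-set enrichment. A synthetic-cohort generator with planted ground
    truth emulates the multi-platform study design and supports calibration
    and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
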