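Package: snapstate
Title: Data-Driven Disease States from Longitudinal Complaint Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis-free discovery of disease states from longitudinal
    electronic-health-record complaint mentions. Patient timelines are segmented
    into 30-day snapshots, vectorized with log term-frequency/inverse-document-
    frequency weighting, and partitioned with K-means. Stable cluster counts are
    selected by bootstrapped cluster stability (data-point-weighted Jaccard
    overlap and a semantic-vocabulary analogue), organised into a cross-K
    hierarchy, and characterised by significantly over-represented complaints,
    grouped clinical phenotypes, demographics, and present/future clinical-event
    risk. Patient-level state co-occurrence odds ratios and first-occurrence
    ordering probabilities yield a directed temporal progression network. A
    synthetic-cohort generator with known latent states, hierarchy, transition
    structure, and event enrichment provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    MASS,
    igraph,
    ape,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
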