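Package: phasecycle
Title: Time-Course Differential Expression and Trajectory Clustering for
    Behavioral Phase Transitions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for brain gene expression time courses across
    experimentally induced transitions between reproductive and brood-care
    phases in clonal ant colonies. Implements spline-based negative binomial
    likelihood-ratio tests for time and time-by-transition effects, P-spline
    mixed-effects mixture clustering of expression trajectories with BIC
    model selection, maximum-change-vector summaries of trajectory timing, a
    bipartite cluster-membership network with a permutation-defined conserved
    sub-network, Fisher enrichment of clusters for gene sets and
    transcription-factor binding sites, and a synthetic-data generator that
    emulates the two-transition brood-swap design with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    splines,
    MASS,
    mclust,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
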