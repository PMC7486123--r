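Package: blamap
Title: Discrete and Graded Excitatory-Neuron Heterogeneity in the Basolateral Amygdala
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for resolving discrete (lateral vs basal
    amygdala) and graded (within-nucleus) heterogeneity among excitatory
    neurons. Covers single-cell RNA-seq quality control, CPM normalization,
    variable-gene selection, PCA, shared-nearest-neighbour Louvain clustering,
    Wilcoxon/Bonferroni marker detection and random-forest subsample
    classification; landmark Procrustes registration of segmented cells onto
    section templates with subregion assignment; image-stage segmentation and
    counts-per-area (CPA) quantification of multiplexed FISH with FFT
    round-to-round registration; the phenotype-index and distance-binned
    correlation-profile statistics; and Monte-Carlo null models for projection
    enrichment and spatial restriction. A seeded synthetic-data generator
    emulates the statistical structure each stage assumes so the full pipeline
    is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    randomForest,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mgcv,
    mclust,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
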