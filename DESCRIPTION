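Package: gliaxes
Title: Dual-Axis Decomposition of Microglial Ageing and Plaque Phagocytosis States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for separating the transcriptional programme of
    amyloid-plaque-phagocytic (XO4+) microglia from that of microglial ageing
    in bulk and single-cell RNA-seq. Provides covariate-decomposed
    negative-binomial differential expression with likelihood-ratio tests,
    FDR-weighted "gene cytometry" scoring, consensus clustering with
    random-matrix cluster-number estimation, diffusion-map pseudotime
    restricted to axis-specific gene sets (a dual ageing/phagocytosis
    decomposition), MST-based lineage pseudotime with a downsampled
    median-rank bootstrap, rank-AUC regulon activity scoring with mixture
    binarization and pruning, expression-matched module scores with
    patient-level cluster statistics, correlation-based projection of single
    cells onto bulk references, and gene-set overlap statistics. A
    negative-binomial count simulator with two latent axes (continuous ageing,
    switch-like phagocytosis) supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    igraph,
    stats,
    utils,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
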