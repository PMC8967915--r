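Package: scqckit
Title: Quality Control Pipeline for Droplet-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A standardized quality-control workflow for single-cell RNA-seq
    count matrices. Imports gene-by-barcode matrices from common preprocessing
    outputs (CellRanger v2/v3, STARsolo, BUStools, dropEst, generic MEX,
    delimited text, h5ad), detects empty droplets with a barcode-rank
    knee/inflection estimator and a Monte-Carlo ambient-pool multinomial test,
    computes per-cell QC metrics and gene-set percentages, scores doublets
    with a simulation/k-nearest-neighbour scorer, a binarized co-expression
    score, a gradient-boosted classifier and their hybrid, estimates per-cell
    ambient-RNA contamination with an EM mixture model and produces
    decontaminated counts, flags outliers by median absolute deviation,
    renders self-contained HTML reports, and exports annotated results to
    flat files or h5ad with full parameter and seed provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scater,
    mclust,
    xgboost,
    FNN,
    uwot,
    cluster,
    ggplot2,
    base64enc,
    digest,
    yaml,
    jsonlite,
    rhdf5,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
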