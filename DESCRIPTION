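Package: clustgauge
Title: Parameter Sweeps and Intrinsic Validity Metrics for Single-Cell
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies how graph-based community-detection parameters
    (number of principal components, neighborhood size, resolution,
    neighborhood method and distance metric) affect clustering accuracy in
    single-cell RNA-seq data, and predicts that accuracy from fifteen
    intrinsic cluster-validity indices.  Provides a negative-binomial
    synthetic-data generator with known cell labels, stratified
    subsampling, a standard preprocessing chain (gene filtering,
    library-size normalization, highly-variable-gene selection, PCA,
    Gauss/UMAP neighbor graphs), a full-factorial Leiden clustering sweep,
    ground-truth scoring (accuracy, adjusted Rand index, normalized mutual
    information), robust Huber regression of accuracy on the sweep factors
    with first-order interactions, and elastic-net prediction of accuracy
    from the validity indices with intra- and cross-dataset validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    methods,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
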