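Package: mscpop
Title: Single-Cell Heterogeneity Analysis of Cultured Mesenchymal Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting subpopulation heterogeneity in
    cultured mesenchymal stromal cell (MSC) populations profiled by droplet
    single-cell RNA sequencing. Provides 10x-style sparse UMI matrix input and
    output, median-absolute-deviation outlier filtering of cells and mean-UMI
    filtering of genes, log-normalization and regularized negative-binomial
    Pearson-residual variance stabilization, cell-cycle module scoring with
    expression-matched control gene bins, per-donor per-phase consensus
    selection of highly variable genes, linear regression of cycle and batch
    covariates, PCA, shared-nearest-neighbor graph construction and Louvain
    modularity clustering, Wilcoxon rank-sum marker detection with
    Benjamini-Hochberg correction, and marker-panel lineage potency scoring
    with density-based bimodal thresholds. A negative-binomial simulator with
    known cluster, batch, cycle and marker-module structure makes every stage
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
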