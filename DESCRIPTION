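Package: scmodules
Title: Cluster Markers and Co-Expression Modules for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for comparing two representations of single-cell
    RNA-seq data: cluster-level marker analysis (one-vs-rest Wilcoxon
    differential expression with log-fold-change, detection-fraction,
    Jaccard and Tau specificity summaries, and Random Forest label
    transfer) and module-level weighted gene co-expression network
    analysis (metacell aggregation, soft-power adjacency, topological
    overlap, average-linkage tree cut with kME rescue, module eigengenes,
    hub genes, permutation-based module preservation Z-summary).
    Includes cross-representation comparison statistics (DEG-module
    Jaccard, cross-condition overlap coefficients, program consolidation,
    local hypergeometric gene-set enrichment) and a seeded negative
    binomial simulator that plants cluster and module structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
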