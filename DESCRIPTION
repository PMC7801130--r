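Package: cartatlas
Title: Single-Cell Transcriptomic Characterization of CAR T-Cell Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell RNA-seq characterization of
    chimeric antigen receptor (CAR) T-cell products: quality control, calling
    of CAR-expressing cells from a vector-derived pseudo-feature, normalization
    and highly-variable-gene selection, graph-based clustering with a
    modularity-resolution scan, batch-balanced k-nearest-neighbour label
    transfer from product to leukapheresis cells, per-gene Welch differential
    expression with joint FDR/fold-change/mean filters, gene-signature scoring
    with expression-binned control genes and exhaustion classification,
    hypergeometric over-representation statistics and pre-ranked gene set
    enrichment analysis with the classic running-sum statistic. Includes a
    multi-donor, multi-condition synthetic count-matrix generator with planted
    ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RANN,
    uwot,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
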