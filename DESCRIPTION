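Package: sipsic
Title: Pathway Activity Scoring for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-cell pathway activity scores from single-cell
    RNA-seq expression matrices using the SiPSiC algorithm: each gene is
    normalized by the median expression of its top tau percent of cells
    (falling back to the gene maximum when that median is zero) and genes
    in a set are aggregated with weights given by their rank of total
    expression across cells. Includes the surrounding analysis protocol:
    cell and gene filtering, CPM normalization, de-logging of published
    log-scale matrices, pairwise differential pathway analysis with
    Benjamini-Hochberg FDR and a max-FDR direction-call rule, pathway-space
    Z-scores, heatmap ordering, Louvain clustering and UMAP embedding of
    cells in pathway space, and a negative-binomial synthetic-data
    generator with planted pathway shifts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    uwot
Suggests:
    fgsea,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
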