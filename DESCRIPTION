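Package: satkit
Title: Saturation Analysis for Single-Cell RNA-Seq Atlas Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether a single-cell RNA-seq dataset has sampled enough
    cells to saturate cluster discovery. Implements nested downsampling of a
    UMI count matrix, Louvain-Jaccard graph clustering in significant
    principal-component space, cluster preservation / conservation / split
    metrics computed from pairwise cluster-overlap tables, a complexity index
    summing the branch lengths of a dendrogram over cluster centroids, and an
    R-squared truncation scan that issues a saturation verdict. Includes
    readers for 10x Genomics Matrix Market and HDF5 gene-barcode matrices and
    a negative-binomial simulator of hierarchically clustered count data for
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
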