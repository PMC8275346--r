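Package: invatac
Title: Invariant Latent Representations for Single-Cell ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of single-cell chromatin
    accessibility (scATAC-seq) profiles that are invariant to technical
    confounders such as sequencing depth and batch, using a conditional
    variational autoencoder trained with a mutual-information penalty
    approximated by pairwise Kullback-Leibler divergences between
    per-cell posteriors. Includes a log-normal read-sampling simulator
    with planted cell types and batches, binarization and bin/cell
    quality-control filters, KNN-graph Louvain clustering, confounder-free
    imputation of accessibility landscapes, and an evaluation suite
    (Dice similarity against bulk truth, nonparametric k-nearest-neighbor
    mutual-information estimators, ARI/NMI clustering agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
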