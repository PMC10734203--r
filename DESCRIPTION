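Package: stens
Title: Ensemble k-NN Imputation of Unmeasured Genes in Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the expression of spatially unmeasured genes in
    imaging-based spatial transcriptomics (MERFISH, osmFISH, STARmap and
    similar panels) by ensembling k-nearest-neighbour regressions over
    multiple scRNA-seq reference datasets, ten expression-similarity
    measures and several neighbourhood sizes, with per-sub-reference
    weights learned from how well each sub-reference predicts the genes
    the two modalities share. Includes a cross-validation harness for
    spatially measured genes, and a downstream pipeline that groups genes
    into spatial expression patterns via Moran's I filtering, a
    self-loop-augmented spatial cross-correlation index, graph clustering,
    and a dip-test-gated search for novel patterns among predicted genes.
    A seeded synthetic-data generator with layered and scattered ground
    truth patterns supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    FNN,
    igraph,
    jsonlite,
    yaml,
    optparse,
    withr,
    rhdf5,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    boot
Config/testthat/edition: 3
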