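Package: phopt
Title: Sequence-Based Prediction of Enzyme Optimal pH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the optimal catalytic pH of an enzyme from
    its amino-acid sequence alone. Implements measurement curation (range
    midpointing, standard-deviation filtering, growth-pH aggregation over
    organisms), four leakage-controlled train/validation splitting strategies
    (random, homology via density clustering on pairwise identity distances,
    PFAM-family hold-out, and EC-class cross-validation), a k-mer summary-table
    baseline predictor, averaged one-hot sequence embeddings with a pluggable
    adapter contract for external embedders, k-nearest-neighbour and
    gradient-boosted-tree regression with grid-search model selection, and a
    delta-vicinity filtered evaluation protocol with stratified reporting.
    A synthetic-data generator produces clustered protein families with known
    labels so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    xgboost,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
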