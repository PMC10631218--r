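Package: convboost
Title: Hybrid Convolutional Network and Gradient-Boosted Tree Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a block-structured one-dimensional convolutional network on
    labeled sequence, time-series, or text data, re-expresses the data as the
    activations of a chosen internal layer, and fits a gradient-boosted tree
    classifier on that learned representation. Includes the search procedures
    for choosing the number of convolutional blocks and the extraction layer,
    deep-only and trees-on-raw baselines, sample-size learning curves, and
    synthetic data generators (planted DNA motifs, class-conditioned sensor
    signals, biased token streams) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
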