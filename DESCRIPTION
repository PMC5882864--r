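Package: choicenet
Title: Distributed Economic Choice in a Small Feedforward Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates two-gamble risky-choice behaviour with a small layered
    tanh network trained trial-by-trial by a chosen-unit-gated variant of
    backpropagation, and provides the population-level statistical readouts
    used to characterise distributed value coding: per-unit single-regressor
    tuning, layer-wise correlations of regression coefficients, choice
    probability correlations, a fixed-expected-value ("common currency")
    probe, psychometric (tanh) choice curves, and simulated lesions with
    graceful-degradation summaries. All study inputs are generated
    internally from discrete reward and probability grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
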