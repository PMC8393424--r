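Package: sdnn
Type: Package
Title: Stimulus-Dependent Attractor Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and mean-field analysis of Hopfield-type binary
    attractor networks driven by a persistent external stimulus field.
    Provides Hebbian storage of random, correlated, or asymmetrically
    diluted pattern sets, zero-temperature sequential spin dynamics with a
    compiled inner loop, replica-symmetric saddle-point solvers at finite
    and zero temperature with Maxwell branch selection, and experiment
    drivers that calibrate the stimulus intensity by maximizing the gap
    between the overlaps obtained under a memory-correlated and an
    orthogonal stimulus.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
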