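Package: switchssm
Title: Switching State-Space Models with Structured Variational Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference and learning for switching linear-Gaussian state-space
    models: a pool of parallel Gaussian state-space models whose emissions are
    selected per time step by a hidden Markov chain. Implements the structured
    variational approximation with g/h fixed-point iterations, a leave-one-out
    (interpolated density) initialization of the E-step, deterministic
    annealing, and generalized EM parameter learning with tied parameters
    across candidate models. Includes classical comparators (static switching,
    interacting multiple models, observation-switching Gaussian merging),
    state-space oscillator model builders, Monte-Carlo segmentation benchmarks,
    and an unsupervised sleep-spindle detector for single-channel EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    readr,
    optparse
Config/testthat/edition: 3
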