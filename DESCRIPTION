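Package: fretdyn
Title: Conformational-State Analysis for Single-Molecule FRET with Binding and Pulling Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for resolving protein conformational
    states from single-molecule FRET trajectories: Gaussian-emission hidden
    Markov models fitted per trace by maximum likelihood (Baum-Welch) or
    variational Bayes, evidence-based selection of the number of states,
    Viterbi idealization, transition-density compilation, threshold-based
    state populations, modal efficiencies, dwell times and group comparisons.
    Companion modules simulate and fit one-site isothermal titration
    calorimetry isotherms, and provide a one-dimensional overdamped Langevin
    analog of constant-velocity steered pulling together with rupture
    (turning-point) and distance-step changepoint detectors. A synthetic-data
    generator (intensity traces, dual-view image stacks, titration heats,
    force/distance series) makes every stage testable against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    tiff,
    withr,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
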