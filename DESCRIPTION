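Package: sacclearn
Title: Sensorimotor Statistical Learning Analysis for Saccadic Hidden-Target Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for saccadic hidden-target
    experiments in which observers localise the unseen mean of a circular
    (von Mises) hint distribution with pro- or anti-saccade responses.
    Provides a synthetic-data generator with parameterised agents, angular
    preprocessing and exclusion rules, learning curves and an ideal-observer
    lower bound on absolute angular error, BIC-based comparison of lagged
    regression models of trial-by-trial guesses, forward stepwise selection
    with cross-validated RMSE, and motor-error-corrected analyses of
    knowledge transfer across a response-modality switch, including a
    three-way repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
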