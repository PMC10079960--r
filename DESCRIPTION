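Package: revbandit
Title: Choice Models and Neural Encoding Analysis for Serial-Reversal Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for two-alternative forced-choice
    serial-reversal (probabilistic bandit) experiments with paired calcium
    imaging. Provides a task simulator with reward-sensitive agents,
    maximum-likelihood fitting and AIC/BIC comparison of trial-by-trial choice
    models (Q-learning with forgetting, logistic regressions, recursive
    logistic regression, win-stay/lose-shift with lapse), behavioral stay
    metrics, a spline-basis penalized linear encoding model for single-neuron
    fluorescence traces with chunked trial-stratified cross-validation and
    one-standard-error lambda selection, tuning indices, and pathway-level
    root-mean-square kernel statistics with BCa bootstrap inference. Includes
    generators for synthetic sessions, calcium traces and head-velocity series
    with stored ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    splines,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
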