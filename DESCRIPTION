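Package: predpursuit
Title: Predictive Smooth Pursuit Analysis with Trial-History Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for predictive smooth pursuit eye movements
    recorded during triangular-waveform (ramp) tracking. Converts 1 kHz eye
    position traces into filtered velocity and acceleration (central
    difference, 30 Hz FIR low-pass, acceleration-criterion saccade removal
    with linear interpolation, 40 ms moving average), detects per-trial
    predictive-pursuit events (eye deceleration onset, timing of eye
    reversal, mean eye deceleration) with steady-state-referenced thresholds
    and exclusion rules, and quantifies stimulus- and behavioral-history
    effects on eye-reversal timing via a node (UPPER/LOWER) classification
    with paired tests and a grid of linear mixed-effects models selected by
    AIC, with variance-inflation diagnostics and within-subject correlations.
    Includes a synthetic eye-trace generator with known ground-truth events
    and history weights so that every stage is testable without human
    recordings, plus normalization, pooled-histogram, and dip-statistic
    unimodality tools for response distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
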