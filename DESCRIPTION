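Package: gaitretrain
Title: EMG Biofeedback Gait Retraining and Knee Contact Force Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for muscle-coordination gait retraining
    experiments in which walkers receive per-step haptic biofeedback to
    reduce gastrocnemius electromyography (EMG). Covers EMG conditioning
    and maximum-voluntary-contraction normalization, ground-reaction-force
    step segmentation, the adaptive per-step vibration feedback controller
    and session qualification rules, 50-step analysis-window and
    representative-step selection, activation-squared static optimization
    on a reduced sagittal-plane musculoskeletal model (plain and
    EMG-constrained), joint-reaction knee contact force with peak and
    impulse metrics, normality-gated paired statistics with
    Benjamini-Hochberg false-discovery-rate control and paired-t power
    analysis, and a synthetic gait-cohort generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
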