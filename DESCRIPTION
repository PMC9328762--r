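Package: tachorace
Title: Race-Model Simulation and Tachometric-Curve Analysis for Urgent
    Saccade Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing urgent prosaccade and antisaccade behavior.
    Simulates a two-plan accelerated race-to-threshold model of saccadic
    choice with exogenous (cue-driven) and endogenous (goal-driven)
    modulation, builds tachometric curves (choice accuracy as a function of
    raw processing time) with sliding bins and exact binomial confidence
    intervals, fits sigmoid and drop-recover psychometric functions by mean
    absolute error, compares curves by an optimal time-shift analysis,
    conditions performance on target-location history, and provides
    trial-level bootstrap and permutation resampling. A synthetic trial
    generator with known ground truth supports end-to-end validation of the
    pipeline without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
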