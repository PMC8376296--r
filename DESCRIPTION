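Package: cuevigor
Title: Cue-Evoked Approach Vigor Encoding in Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how cue-evoked neuronal firing encodes the vigor of
    reward-seeking locomotor approach in operant discriminative-stimulus
    tasks. Provides movement-bout segmentation from two-LED head tracking via
    a locomotor index and Gaussian-mixture thresholds, trial-level kinematic
    and behavioral-state feature extraction, peri-cue excitation detection
    with baseline confidence criteria, factor-analytic selection of
    non-redundant regressors, per-neuron Poisson generalized linear models
    with interdecile-range firing-difference effect sizes, population-level
    inference with Holm correction, pre/post-infusion epoch regression, and a
    fully parameterized synthetic-session simulator with exported ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
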