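Package: rulexgaze
Title: Mixture Modeling of Similarity- and Rule-Based Judgment with
    Looking-at-Nothing Gaze Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiple-cue quantitative judgment experiments that
    combine cognitive modeling with eye tracking. Implements the RulEx-J
    mixture model, which blends a similarity-to-exemplars prediction and a
    rule-based linear prediction through a mixture weight alpha, fit per
    participant by maximum likelihood with stimulus-wise cross-validation.
    Provides the multiple-cue task environment (multiplicative and additive
    criterion functions, exemplar sets, trial schedules, staircase
    calibration), looking-at-nothing gaze metrics over screen areas of
    interest (duration, strength, time-binned profiles, split-half
    reliability), a synthetic cohort generator coupling alpha to gaze, a
    parameter-recovery simulation suite, and the statistical layer (Kendall
    rank correlations, rank-sum group comparisons, Fisher-z sensitivity
    power analysis, report assembly) used to relate model parameters to
    gaze behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
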