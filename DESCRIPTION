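Package: gcbm
Title: Gamified Cognitive Bias Modification Training: Task Engine, Simulated
    Participants and Trial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an emotion-recognition cognitive bias modification
    (CBM) training task on a happy-sad morph continuum, including the
    gamified (points-based) variant: block scheduling, balance-point
    estimation, target setting, text feedback and proximity-weighted point
    scoring. Provides a psychometric agent model (logistic decision
    criterion with feedback-driven learning) and a synthetic cohort
    generator for desk-scale randomized-trial simulations, plus the
    trial's statistical pipeline: Tukey-fence outlier filtering,
    group-by-time mixed ANOVA, baseline-adjusted pairwise regressions,
    descriptives, and a-priori power computation via the noncentral t
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
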