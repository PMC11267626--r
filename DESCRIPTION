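Package: harmonex
Title: Harmonization of Questionnaire Scores by Equating, Item Response
    Theory and Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Puts scores from a short polytomous rating scale onto the scale
    of a longer one measuring the same construct, using the single-group
    (common-persons) design: mean, linear, equipercentile and Gaussian-kernel
    observed-score equating; a Generalized Partial Credit Model crosswalk
    (marginal maximum likelihood EM estimation, expected a posteriori trait
    scoring, expected sum score); and machine-learning mappers (linear and
    cumulative-logit ordinal regression, random forests, support vector
    machines) across sum-to-sum, items-to-sum and items-to-items mapping
    settings. Methods are compared by k-fold cross-validated RMSE, with
    Guttman's lambda-2 reliability guiding the harmonization direction. A
    calibrated synthetic-data generator emulates a general-population
    two-scale ADHD screening sample, so the whole pipeline is testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
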