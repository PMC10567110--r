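Package: metacogtrack
Title: Simulated Treatment Studies of Metacognitive Bias in Anxious-Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how metacognitive bias (mean confidence on a
    perceptual decision task) tracks transdiagnostic psychiatric symptom
    dimensions across treatment. Implements a two-down one-up adaptive
    dot-difference staircase in log space with signal-detection-theory
    observers, a synthetic three-arm two-timepoint cohort generator with
    item-level questionnaire responses, weighted transdiagnostic dimension
    scoring, task-metric extraction with data-quality exclusions, and the
    full repeated-measures statistical pipeline (cross-sectional regression,
    random-intercept change models, time-by-change interactions, group-by-time
    ANOVA, change-score correlations, Welch and one-way summary tests, exact
    contingency-table tests, and correlation power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    lme4,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
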