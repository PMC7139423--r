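Package: scedab
Title: Analysis of ABAB Single-Case Designs with Momentary Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing ABAB (withdrawal/reversal) single-case
    experimental designs measured by repeated momentary assessments.
    Covers questionnaire scoring (six-item state-anxiety short form on a
    visual-analog metric, Likert behavior ratings with item reversal),
    phase-wise descriptive statistics, the percentage of data points
    exceeding the baseline median (PEM), split-middle baseline trends with
    stability envelopes, median-absolute-deviation variability comparison,
    regression-tree level segmentation, nonoverlap of all pairs (NAP) with
    asymptotic confidence intervals and carryover flagging, and a
    design-comparable between-case standardized mean difference (BC-SMD)
    estimated by restricted maximum likelihood with a small-sample
    correction and time-of-day stratification. A synthetic
    momentary-assessment generator with known ground truth supports
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
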