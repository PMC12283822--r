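Package: survarmeta
Title: Arm-Level Variability Meta-Regression for Time-to-Event Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess treatment-effect heterogeneity in placebo-controlled
    survival trials from published Kaplan-Meier curves. Reconstructs individual
    participant time-to-event records from digitized survival-curve coordinates
    and number-at-risk tables (the Guyot algorithm), fits right-censored Weibull
    models separately per trial arm, derives the log standard deviation of the
    event-time distribution with a delta-method sampling variance, and fits an
    inverse-variance-weighted random-intercept meta-regression of log(SD) on
    treatment adjusted for log(Mean), including per-predictor
    treatment-interaction screens. A trial simulator with known ground truth
    supports calibration and validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
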