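Package: trajcast
Title: Weighted Gradient-Offset Forecasting of Longitudinal Biomarker
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forecasts the next value of multimodal longitudinal biomarkers
    from two prior follow-up visits using a weighted gradient-offset linear
    predictor: class-average base gradients describe typical piecewise-linear
    progression, per-subject deviations from them (gradient offsets) are
    propagated to the next follow-up interval through a least-squares weight
    matrix averaged over leave-one-out folds, and a linear support vector
    machine suggests the base class for new subjects.  Completed trajectories
    feed a second linear SVM that separates progressing from stable subjects
    in a nested cross-validation over incrementally grown, t-test-ranked
    marker subsets.  Includes a synthetic longitudinal cohort simulator with
    known coupling structure for parameter-recovery and benchmarking studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
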