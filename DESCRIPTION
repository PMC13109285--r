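Package: micfim
Title: Anchor-Based Minimal Important Change Estimation for the
    Functional Independence Measure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the minimal important change (MIC) of the
    Functional Independence Measure (FIM) motor, cognitive and total
    scores from a dichotomous discharge-destination anchor.  Implements
    the ROC/Youden-index cutoff, the predictive-modeling estimator
    MIC_pred = (ln(odds_pre) - C)/B from a logistic regression of the
    anchor on the change score, and its prevalence-bias adjustment
    MIC_adj = MIC_pred - S*ln(odds_pre) with
    S = 0.09*SD + 0.103*SD*Cor, together with percentile bootstrap
    confidence intervals, floor/ceiling screening at baseline, a
    moment-matched two-group normal synthetic-cohort generator, and a
    Monte-Carlo estimator-recovery study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
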