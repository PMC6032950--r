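Package: labourdx
Title: Labour Progression Modelling and Diagnostic Accuracy of Partograph
    Reference Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how well cervical-dilatation-over-time
    classifiers predict severe adverse birth outcomes. Provides a calibrated
    synthetic cohort generator for intrapartum panel data, WHO partograph
    alert- and action-line crossing classification, the 10-group Robson
    obstetric classification, progressive multi-state Markov models of
    cervical dilatation fitted to panel-observed exam series, customised
    percentile labour curves derived as first-passage-time quantiles, and
    diagnostic accuracy statistics (sensitivity, specificity, likelihood
    ratios, diagnostic odds ratio, Youden's J) with the confidence interval
    methods used in the intrapartum-monitoring literature, plus an
    end-to-end analysis pipeline with ROC-space output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
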