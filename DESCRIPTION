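Package: lumipath
Title: Surface-Luminance Image Analysis for Tissue Lesion Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing calibrated surface-luminance maps of tissue
    samples: luminance-band (pseudo-colour) segmentation, connected-component
    lesion-focus detection, per-sample luminance summaries, and a full
    diagnostic-accuracy evaluation of maximum-luminance (Lmax) threshold
    classification against a histopathology reference (contingency tables,
    sensitivity/specificity/predictive values/likelihood ratios, threshold
    sweeps, ROC curves with trapezoidal AUC, chi-squared association and
    Cramer's V, rank-based group comparison, and AUC-based sample-size
    calculation). Includes a synthetic phantom generator and cohort
    simulator so every stage is testable without measurement hardware, plus
    a command-line interface tying image analysis to diagnostic reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
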