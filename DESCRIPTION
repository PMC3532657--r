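Package: residuoscope
Title: Wide-Field Fluorescence Quantification for Image-Guided Resection of
    Microscopic Residual Tumor
Version: 0.1.0
Authors@R:
    person("residuoscope", "developers", email = "residuoscope@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative intraoperative wide-field fluorescence
    imaging: exposure-time normalization of CCD counts to emission rates,
    device linearity calibration, contrast-transfer-function (CTF) analysis of
    bar resolution targets, tumor-to-muscle signal ratios, per-subject
    residual-disease thresholding at a fraction of the tumor minimum emission
    rate, simulation of an iterative image-guided resection loop, and
    Kaplan-Meier / log-rank / hazard-ratio analysis of local recurrence.
    Includes a seeded synthetic-phantom and cohort generator so the whole
    pipeline can be exercised end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
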