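Package: pdacgrowth
Title: Pre-Diagnostic Growth Kinetics and Metabolic Profiling of
    Pancreatic Cancer Imaging Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gompertz modelling of serial CT lesion volumes in pancreatic
    ductal adenocarcinoma (PDAC). Estimates per-patient growth-rate
    constants by Levenberg-Marquardt nonlinear least squares, projects
    tumor initiation times backward from a single cell to a detectable
    mass, characterizes cohort initiation-time distributions by lognormal
    maximum likelihood, classifies imaging subtypes (high/low delta) from
    the growth-rate constant with ROC analysis and leave-one-out
    cross-validation, and compares soft-tissue wasting rates and blood
    glucose trends between subtypes. Includes a synthetic cohort
    generator emulating the statistical structure of serial
    pre-diagnostic imaging data, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    fitdistrplus
Config/testthat/edition: 3
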