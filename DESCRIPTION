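Package: spacerdose
Title: Rectal Dose-Reduction Prediction and Patient Selection for
    Hydrogel Spacer Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Decision-support tooling for managing perirectal hydrogel
    spacer implants in hypofractionated (60 Gy / 20 fraction) prostate
    radiotherapy.  Builds the standard planning structures (PTV with
    anisotropic margins, rectal-wall shells, height-limited walls) from
    per-slice contour stacks, computes geometric predictors (rectum-in-PTV
    overlap, slice-wise Hausdorff rectal-wall-to-CTV distance) and rectal
    dose endpoints (RV55Gy before implant and its pre-to-post change),
    fits and validates multiple linear models by backward stepwise AIC
    with variance-inflation pruning, structure coefficients and
    leave-one-out cross-validation, and ships published predictive models
    with nomograms and a two-stage patient-selection flowchart.  A
    synthetic phantom and cohort generator makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
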