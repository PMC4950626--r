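Package: iphdetect
Title: Semi-Automatic Intraplaque Hemorrhage Detection and Quantification
    on T1-Weighted Carotid MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies carotid intraplaque hemorrhage (IPH) on
    heavily T1-weighted (MP-RAGE) vessel-wall MR slices by reference-normalized
    intensity thresholding inside a reviewer-drawn outer-wall contour. Supports
    three normalization references (sternocleidomastoid muscle mean, adjacent
    deep-muscle mean, and the local median within a 4 cm circular region of
    interest centered at the carotid lumen), selects the operating threshold by
    maximizing Youden's index on an ROC curve against histology ground truth,
    and evaluates generalization by patient-level leave-one-out
    cross-validation. Includes a synthetic phantom generator with known IPH
    geometry, calcification, surface-coil sensitivity falloff and noise, so the
    full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
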