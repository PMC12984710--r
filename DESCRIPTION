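Package: octits
Title: Iterative Teacher-Student Semi-Supervised Classification for Retinal OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, backbone-pluggable implementation of confidence-filtered
    self-training (the iterative teacher-student scheme) for three-class
    retinal OCT B-scan classification (normal / drusen / CNV), together with
    the experimental harness such a study needs: patient-wise grouped data
    splitting with nested label-fraction subsetting, class-weighted training
    with learning-rate reduction and early stopping, pseudo-label reliability
    filtering by confidence threshold, multiclass confusion-matrix metrics and
    per-class, micro- and macro-average ROC analysis. A synthetic OCT-phantom
    cohort generator with the patient/volume/B-scan hierarchy makes the whole
    pipeline exercisable at desk scale without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    png,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
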