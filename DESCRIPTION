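Package: softmark
Title: Facial Soft-Tissue Landmark Detection and Clinical Equivalence Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated localization of facial soft-tissue landmarks on
    frontal and profile 2D face images with a coordinate-regression
    convolutional network, together with the clinical-equivalence evaluation
    layer used to compare automated and manual annotation: millimetre
    calibration, per-landmark error tables, success rates at clinical
    thresholds, cumulative error distributions and their area (AUC-CED), two
    one-sided tests (TOST) of equivalence, Bland-Altman agreement, and
    intraclass correlation for intra-observer repeatability. Includes a
    synthetic face-cohort generator with exact ground-truth landmarks and a
    simulated annotator so the full pipeline is exercisable without patient
    data, plus readers and writers for LabelMe-style point annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
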