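Package: bsiquant
Title: Automated Bone Scan Index Quantification from Whole-Body Scintigrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies metastatic skeletal tumour burden on whole-body planar
    bone scintigrams. Fits a sex-specific skeletal atlas to paired
    anterior/posterior images by multi-scale non-rigid registration, detects
    hot spots with a locally adaptive threshold, classifies each hot spot with
    per-region neural networks, and aggregates probabilities and per-region
    skeletal involvement into a patient-level abnormality score and the bone
    scan index (BSI). Ships a seeded synthetic scintigram phantom generator
    with ground-truth lesion labels for end-to-end validation, plus the
    statistical toolkit used to compare scoring systems: empirical ROC with a
    Youden-style optimal cutoff, paired AUC comparison (DeLong), proportion
    tests, and net reclassification improvement over ordered risk categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
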