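Package: tissuescore
Title: Digital PD-L1 (22C3) Tumor Proportion Scoring with Immune-Cell
    Recognition and CLIA-Style Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open digital-pathology pipeline for scoring PD-L1 (22C3)
    immunohistochemistry in non-small-cell lung cancer: color deconvolution
    of brightfield slides into hematoxylin and DAB optical-density planes,
    nucleus detection and cellular biofeature extraction, machine-learning
    separation of tumor and stroma compartments from analyst-circled
    training regions, membrane-intensity thresholding into ordinal staining
    grades, Tumor Proportion Score computation with therapy binning,
    macrophage and lymphocyte classifiers trained from co-registered
    dual-immunofluorescence ground truth, and the validation statistics of
    a CLIA-style study (cell-level sensitivity and specificity, treatment
    bin concordance, intraclass-correlation precision with simulated
    confidence intervals, Bonferroni-corrected Pearson concordance). A
    synthetic-slide generator with complete cell-level ground truth supports
    development and validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    grDevices,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
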