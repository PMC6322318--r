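Package: cpradiomics
Title: MRI Radiomics for Craniopharyngioma Subtype and Mutation Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end MRI radiomics analysis for classifying
    craniopharyngioma histological subtype (adamantinomatous vs papillary)
    and somatic mutation status (BRAF V600E, CTNNB1) from segmented tumor
    volumes. Extracts 1021 features per case (intensity, shape, texture,
    wavelet sub-band, atlas-relative location, clinical), screens image
    features for segmentation robustness by perturbing the region of
    interest and thresholding the intraclass correlation coefficient,
    ranks features by bootstrapped random-forest impurity importance,
    selects a subset by sequential forward selection under cross-validated
    accuracy, evaluates random-forest vote-fraction scores with ROC and
    confusion-matrix metrics, and reports logistic nomograms with point
    scales and Harrell's C-index. Includes a seeded synthetic-cohort
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    RNifti,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
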