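Package: radbiopsy
Title: MRI Radiomics Virtual Biopsy for BRAF Genotyping of Melanoma Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Radiomics pipeline for noninvasive ("virtual biopsy") prediction of
    BRAF mutation status of melanoma brain metastases from contrast-enhanced
    T1-weighted MRI. Normalizes lesion intensities to a normal-appearing
    white-matter reference, extracts a fixed 195-feature vector per lesion
    (clinical, atlas-location, 3D morphology, first-order histogram, and
    gray-level co-occurrence texture over 13 spatial offsets), screens features
    with distribution-gated two-group tests, reduces them by principal
    component analysis, and classifies with six support vector machine kernels
    under patient-grouped stratified 5-fold cross-validation. Ships a seeded
    synthetic 3D cohort generator emulating the two-class texture, location and
    demographic structure of the clinical problem so the whole analysis runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
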