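Package: radiomix
Title: PET and MRI Radiomics for Tumor Phenotype and Prognosis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for multi-modality tumor radiomics.
    Loads PET and DCE-MR tumor volumes with aligned masks, resamples to
    isotropic spacing, converts PET activity to standardized uptake values,
    and extracts 42 radiomic features per modality (9 first-order intensity,
    8 three-dimensional shape, 25 gray-level co-occurrence matrix texture
    features averaged over the 13 unique voxel directions). Downstream tools
    cover consensus clustering with CDF-area cluster-number selection,
    chi-squared / Cramer's V, Spearman and variance-explained association
    statistics against clinical outcomes, and repeated stratified nested
    cross-validated classification of recurrence-free survival and tumor
    grade with bootstrap confidence intervals and coefficient-tally feature
    importance. A synthetic cohort generator produces textured ellipsoidal
    tumors with outcome labels coupled to known latent groups so the whole
    pipeline can be exercised and validated without access to patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    mclust,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
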