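Package: habitomics
Title: Intratumoral and Peritumoral Habitat Radiomics for Treatment Response Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Habitat imaging analysis of co-registered multi-sequence MRI for
    predicting pathologic complete response to neoadjuvant therapy. Builds
    tumor and peritumoral-ring subregions ("habitats") by cohort-pooled
    K-means clustering of per-voxel intensity triples with sum-of-squared-error
    elbow model selection, extracts the standard 107-feature radiomic panel
    (shape, first order, GLCM, GLRLM, GLSZM, NGTDM, GLDM) per habitat and
    sequence, and fits cross-validated classifiers after Z-scoring, Pearson
    redundancy filtering and cross-validated LASSO feature selection. Includes
    linear-model SHAP attributions, biomarker association utilities, and a
    synthetic multi-sequence phantom cohort generator with planted habitat
    structure for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    igraph,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
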