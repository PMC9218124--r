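Package: painpsych
Title: Pain-Sensitivity Psychophysics and Brain-Rating Dissociation Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visual-analog-scale (VAS) rating data from
    quantitative sensory testing together with per-subject voxelwise fMRI
    contrast maps. Assigns participants to pain-sensitivity classes with
    Gaussian mixture models selected by a spurious-class rule and BIC,
    fits Stevens power functions to stimulus-response curves in double-log
    space, derives rating-based discrimination thresholds from per-trial
    logistic fits, and relates brain contrast maps to ratings through
    voxelwise covariate GLMs with permutation-based cluster inference,
    signature-expression (dot-product) scoring, and cross-validated
    LASSO principal-component regression. Ships a synthetic cohort and
    beta-map generator with known ground truth so every stage can be
    exercised and calibrated end-to-end without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
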