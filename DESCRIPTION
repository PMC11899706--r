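Package: octradiomics
Title: Radiomics Feature Stability and Classification for Dermatological OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the repeatability and reproducibility of
    handcrafted radiomics features extracted from skin optical coherence
    tomography (OCT) volumes. Implements fixed-bin-size gray-level
    quantization over a grid of bin widths, from-scratch extraction of the
    107 standard first-order, shape and texture features (GLCM, GLRLM,
    GLSZM, GLDM, NGTDM), test-retest repeatability screening with Lin's
    concordance correlation coefficient, Spearman-based redundancy removal,
    cross-bin-width reproducibility counting, and a comparison of
    gradient-boosted multiclass classifiers built from robust features
    versus recursive feature elimination, including a label-randomization
    negative control. A synthetic OCT cohort generator with known
    ground-truth lesion parameters supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml,
    withr,
    knitr
Config/testthat/edition: 3
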