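Package: pkdprog
Title: Serum-Proteomics Prediction of Kidney Function Decline in ADPKD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for serum-proteomics based prediction of
    annual eGFR decline in autosomal dominant polycystic kidney disease
    (ADPKD): CKD-EPI eGFR computation with intervention-aware censoring and
    robust per-patient annualized slopes; preprocessing of long-format DIA
    protein-group reports (q-value filtering, missingness filtering,
    variance-stabilizing normalization, left-censored imputation, PCA
    outlier flagging, empirical-Bayes batch correction); moderated
    association testing and weighted-LASSO stability selection of protein
    markers; linear progression models including transcribed published
    coefficient sets and a Mayo Imaging Classification comparator; and
    benchmarking utilities (RMSE strata, agreement lines, repeatability,
    ROC). A synthetic cohort generator with exported ground truth supports
    recovery testing in place of the non-public registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    limma,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
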