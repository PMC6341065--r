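Package: flowps
Title: Floating-Window Data Trimming for Support Vector Machine Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-test-sample data trimming for support vector machine (SVM)
    classification of clinical response from gene expression. For every
    validation sample the method drops features whose validation projection
    is not flanked by at least m training projections on both sides, keeps
    only the k nearest training samples in the surviving feature space,
    scores every (m, k) cell of the parameter lattice by internally
    cross-validated ROC AUC, and averages SVM predictions over the
    prediction-accountable set of cells whose AUC reaches p * max(AUC).
    Includes single-gene ROC-AUC marker selection with leave-one-out core-gene
    intersection, quantile normalization, class equalization, classical-SVM
    and PCA-assisted SVM baselines, classifier-quality metrics
    (AUC, FDR, Sn, Sp, ACC, MCC at the FP+FN-minimizing threshold), and
    seeded synthetic-data generators for testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    limma,
    FNN,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
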