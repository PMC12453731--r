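Package: cardiofuse
Title: Progressive Attention-Based Fusion of Synchronized ECG and PCG for
    Cardiac-State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-to-beat analysis of synchronized electrocardiogram (ECG)
    and phonocardiogram (PCG) recordings for binary normal/abnormal
    cardiac-state classification. Implements a three-branch 1-D
    convolutional network: two squeeze-and-excitation residual encoders
    (one per modality) and a progressive cross-modal fusion branch that
    combines spatial and channel attention at four feature levels.
    Includes a synchronized ECG/PCG simulator with ground-truth S1
    annotations, WFDB record I/O, S1-to-S1 cardiac-cycle segmentation with
    fixed-length resampling, class-weighted training with plateau learning
    rate decay and early stopping, stratified cross-validation, an
    ablation-variant factory (single-modality, early/late fusion,
    attention-reduced variants), missing-modality evaluation, and
    confusion-matrix/ROC metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
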