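Package: petwsdl
Title: Weakly Supervised Deep Learning Prognosis from PET/CT with
    Positive-Negative-Unlabeled Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic modelling from co-registered FDG-PET/CT
    volumes when a large fraction of the cohort has missing or incomplete
    survival follow-up. Implements a compact 3D residual convolutional
    network for deep-feature extraction from lesion regions of interest,
    positive-negative-unlabeled (PNU) semi-supervised risk estimators that
    derive implicit labels for patients without usable follow-up, a
    weakly supervised retraining pipeline producing the prediction
    similarity index (PSI) prognostic score, conventional PET metabolic
    metrics (SUVmax, SUVmean, MTV, TLG), and a survival evaluation
    battery (Kaplan-Meier, log-rank, IPCW time-dependent ROC, Cox
    proportional hazards, Fisher's exact, median-cutoff univariate
    screening). A synthetic multi-scanner PET/CT cohort simulator with
    class-linked lesion phenotypes and progression-free-survival hazards
    makes the whole pipeline exercisable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    survival,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    glmnet,
    withr
Config/testthat/edition: 3
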