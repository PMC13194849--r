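Package: bmkinetics
Title: Bone-Marrow FDG Kinetics and Prognostic Modelling for Dynamic PET
Version: 0.1.0
Authors@R: person("bmkinetics", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for prognostic analysis of dynamic FDG-PET time-activity
    curves (TACs): forward simulation and weighted nonlinear least-squares
    fitting of the irreversible/reversible two-tissue compartment model,
    decomposition of tissue TACs into vascular, free and metabolized
    components, TAC feature extraction (slopes, AUC, peak features, including
    the bone-marrow free-FDG 10-30 min slope), conventional SUV/MTV/TLG
    metrics, bootstrap-LASSO-Cox stable feature selection with
    optimism-corrected concordance, single-feature risk stratification
    (log-rank optimal cutpoint, Kaplan-Meier), time-dependent ROC,
    calibration and decision-curve evaluation, and a fully synthetic
    dynamic-PET cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
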