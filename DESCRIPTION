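Package: mamil
Title: Modality-Attention Dual-Stream Multiple Instance Learning for
    Multi-Sequence MRI Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weakly supervised classification of 3D lesions from
    multi-parametric MRI. A lesion is treated as a bag of 2D slices
    (multiple instance learning); five co-registered MRI modalities are
    fused by a squeeze-and-excitation modality attention module and
    aggregated by a dual-stream instance aggregator (max-pooled critical
    instance plus similarity-weighted bag embedding). Includes a synthetic
    multi-modal lesion phantom generator, ROI preprocessing, training with
    Adam, stratified cross-validated evaluation with DeLong AUC confidence
    intervals, and an ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    RNifti,
    pROC,
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
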