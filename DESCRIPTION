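Package: eegforest
Title: Directed EEG Connectivity Features and Random-Forest Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits multivariate autoregressive (MVAR) models to multichannel
    EEG segments and derives frequency-domain effective-connectivity
    measures -- generalized partial directed coherence (GPDC) and the
    direct directed transfer function (dDTF) -- averaged over the
    canonical delta/theta/alpha/beta/gamma bands. The resulting directed
    channel-pair features feed a bagged ensemble of Gini decision trees
    with per-tree feature subsampling, evaluated under subject-unaware
    and leave-p-subjects-out cross-validation with ROC/AUC and cross-fold
    Gini-importance summaries. Includes EDF and CSV recording readers,
    Butterworth pre-filtering, fixed-window segmentation, and a synthetic
    MVAR cohort generator with planted directed, band-specific couplings
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
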