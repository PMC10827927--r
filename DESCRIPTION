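Package: ertnet
Title: Interpretable Convolution-Transformer Networks for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for emotion recognition from multichannel
    EEG with a compact hybrid convolution plus transformer classifier (ERTNet).
    Provides EEG ingestion (EDF and array containers), FIR band-pass and notch
    filtering, resampling, epoch segmentation and valence/arousal labelling; a
    synthetic-EEG generator with band- and channel-localised class signatures
    embedded in 1/f noise; the ERTNet architecture with full-width multi-head
    self-attention implemented from first principles, trained by built-in
    backpropagation with Adam; evaluation protocols (stratified k-fold,
    leave-one-subject-out), Wilcoxon signed-rank and DeLong correlated-AUC
    comparisons, and hyperparameter search; and interpretability procedures:
    temporal-kernel frequency responses with band labels, spatial topographies,
    kernel-ablation studies and Gaussian-kernel similarity fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    minpack.lm
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
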