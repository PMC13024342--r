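Package: flowfuse
Title: Cross-Modal Speech-EEG Fusion for Alzheimer's Detection via
    Rectified Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for three-class (Alzheimer's disease, mild cognitive
    impairment, healthy control) classification from speech when EEG is
    only partially observed.  Implements handcrafted EEG biomarker
    extraction (time-domain statistics, band-power descriptors, discrete
    wavelet sub-band features, multiscale sample entropy, phase lag index
    connectivity), dimensionality reduction by PCA and a masked
    autoencoder, domain-adversarial cross-modal alignment of speech and
    EEG features into a shared subspace with center, consistency and
    gradient-reversal losses, conditional rectified-flow generation of
    EEG-like latent representations from speech, and a
    squeeze-and-excitation fusion classifier with one-vs-rest evaluation
    metrics and a cross-validation/ablation harness.  A synthetic-data
    module generates band-structured EEG signals and latent-continuum
    feature cohorts with the missing-modality structure the method
    assumes, so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
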