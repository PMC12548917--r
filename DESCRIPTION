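Package: mifuse
Title: Multi-Scale Fusion Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decodes motor-imagery electroencephalography (EEG) trials with a
    hybrid neural network that combines spatiotemporal convolution,
    inception-style multi-branch separable convolution, multi-head
    self-attention, a dilated causal temporal convolutional network, and
    feature/decision fusion. All layers, back-propagation and the Adam
    optimizer are implemented in base R on top of BLAS matrix products.
    Includes a synthetic event-related-(de)synchronization EEG generator,
    Z-score normalization fitted on training data only, stratified k-fold and
    leave-one-subject-out split planning, training with early stopping and
    max-norm constraints, evaluation (accuracy, Cohen's kappa, confusion
    matrices, Wilcoxon signed-rank comparison), ablation switches for every
    block, and interpretability exports (penultimate-layer embeddings and
    multi-branch kernel spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
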