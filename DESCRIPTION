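Package: boldwct
Title: Wavelet-Coherence Scalogram Classification of Resting-State fMRI
    BOLD Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying autism-spectrum subtypes from resting-state
    fMRI region-of-interest (ROI) BOLD time series. Implements Welch power
    spectral density estimation with one-way ANOVA ranking to select the most
    group-discriminative brain node, complex Morlet continuous wavelet
    transforms with Torrence-Webster smoothing to compute squared wavelet
    coherence between node pairs, rasterization of coherence maps to
    224x224 scalogram images, a compact three-block convolutional neural
    network for binary and four-class scalogram classification, evaluation
    protocols (stratified hold-out, k-fold, leave-one-site-out) with
    macro-averaged metrics, and a synthetic multi-site cohort generator with
    planted spectral-power and phase-coupling group effects for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
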