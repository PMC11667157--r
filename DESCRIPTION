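Package: mi3dnet
Title: Spatial-Spectral Tensor Decoding of Motor Imagery EEG with a
    Pseudo-3D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding left- versus right-fist motor imagery from
    multichannel EEG. Trials are converted into spatial-spectral image
    tensors: per-channel Welch power spectral densities are reduced to
    narrow sub-band powers, arranged on a 2D scalp grid following the
    10-10 electrode montage, and upsampled by triangulation-based
    piecewise-cubic (Clough-Tocher) interpolation into a stack of
    topographic frames. A factorized pseudo-3D convolutional network
    (spatial 5x5x1 and spectral 1x1x5 kernels with square / log-power
    blocks) classifies the tensors. Includes an EDF reader, a generator
    of synthetic trials with lateralized mu-rhythm event-related
    desynchronization, a frequency band-scan optimizer, and
    accuracy / Cohen's kappa / recall / F1 evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
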