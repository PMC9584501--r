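Package: cgcnn
Title: Attention-Modulated Chebyshev Graph Convolutional Networks for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("EEG", "Decoding Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dual-branch (spatial-temporal and spatial-spectral) graph convolutional
    networks for motor-imagery electroencephalography (EEG) classification. Builds an
    electrode-montage graph with 8-neighbourhood adjacency, spectral operators and a
    Chebyshev polynomial basis; converts raw trials into spatial-temporal and
    spatial-spectral graph tensors (Welch power spectral density features); implements
    pairwise attention with row-wise L2 normalization, attention-modulated Chebyshev
    graph convolution, temporal/spectral convolution, global feature aggregation,
    shortcut connections and dual-branch fusion, together with hand-verified
    backpropagation and Adam training; provides sliding-window and white-noise data
    augmentation, leakage-safe stratified 5-fold cross-validation, accuracy and Cohen's
    kappa metrics, a synthetic band-limited EEG generator with 1/f background, and a
    command-line pipeline (simulate, preprocess, train, evaluate, predict).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
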