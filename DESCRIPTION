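Package: semgfusion
Title: Multiscale Time-Frequency Fusion and Deep Belief Classification of Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motion-intention recognition from multichannel surface
    electromyography (sEMG). Generates synthetic multichannel sEMG trials with
    controllable per-class spectral signatures, denoises them (50 Hz notch,
    6 Hz high-pass), builds multiscale time-frequency representations from
    analytic Morlet continuous wavelet transforms fused across channels into
    RGB images, extracts features with a densely connected convolutional
    network, classifies with a deep belief network (stacked restricted
    Boltzmann machines with contrastive-divergence pretraining and supervised
    fine-tuning), and evaluates with subject-wise splits, confusion matrices,
    feature-mutation statistics and correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    generics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
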