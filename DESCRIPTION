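Package: ecgan
Title: SNR-Controlled Noise Synthesis, Adversarial Denoising and Beat
    Classification for Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for single-lead electrocardiogram
    processing: WFDB record input/output with beat annotations, Fourier
    resampling, synthesis of baseline-wander, electrode-motion and
    muscle-artifact noise at exact target signal-to-noise ratios,
    fixed-window segmentation with min-max normalization, a least-squares
    generative adversarial denoiser built on a 1D U-Net of residual
    blocks with a composite distance-augmented generator loss, a 1D
    residual-network beat classifier with transfer learning, and the
    PRD/SNR/RMSE and precision/recall/F1 evaluation suite. Includes a
    synthetic ECG and noise generator so the whole pipeline is testable
    without external databases, and an offline stream simulator for
    window-by-window inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
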