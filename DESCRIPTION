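Package: licoriceNIR
Title: Online NIR Chemometrics for Multi-Phase Licorice Extraction
Version: 0.1.0
Authors@R:
    person("Process Analytics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate calibration toolkit for monitoring the water
    extraction of licorice (Radix Glycyrrhizae) by online near-infrared
    spectroscopy. Implements the full chemometric workflow used in process
    analytical technology for herbal extraction: Kennard-Stone sample set
    partitioning, a ladder of spectral pretreatments (Savitzky-Golay
    smoothing and derivatives, SNV, MSC, orthogonal signal correction,
    wavelet denoising, vector normalization), NIPALS partial least-squares
    regression with leave-one-out cross-validation and PRESS-based latent
    factor selection, moving-window PLS and synergy interval PLS (SiPLS)
    wavelength selection, and phase-wise model assessment (relative errors,
    F test against the reference assay, multivariate detection limit).
    Ships a synthetic extraction-spectra generator so the entire pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
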