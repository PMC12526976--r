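Package: aovmd
Title: Adaptive Variational Mode Decomposition Denoising for Magnetocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Denoising of weak cardiac magnetic-field (magnetocardiography)
    recordings acquired in unshielded environments. Implements variational
    mode decomposition (VMD) via ADMM in the frequency domain, an improved
    arithmetic optimization algorithm (tent-chaos initialization, nonlinear
    accelerated function, population mutation) that selects the decomposition
    level K and penalty factor alpha by minimizing mean envelope entropy, and
    a frequency-aware modal disposal stage (removal, wavelet thresholding,
    baseline correction) followed by reconstruction. Includes a synthetic
    MCG generator, FIR and wavelet-threshold comparator denoisers, and
    cardiac signal-quality metrics (high/low-frequency noise suppression,
    QRS amplitude change, spectral entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
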