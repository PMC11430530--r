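Package: alphadyn
Title: Time-Resolved Spectral Parametrization and Decoding of EEG Alpha
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of ongoing spectral dynamics in
    resting-state EEG. Generates synthetic multichannel recordings whose
    power spectra combine a 1/f-like aperiodic component with an
    alpha-band peak whose centre frequency drifts over time; decomposes
    recorded or simulated signals window-by-window into aperiodic
    (offset, exponent) and Gaussian peak (centre frequency, amplitude,
    width) parameters on short-time Fourier spectra; reduces the
    parameter time series to per-channel variability features and
    pre/post-induction contrasts; decodes group membership from channel
    topographies with a class-balanced leave-one-subject-out linear
    support vector machine, permutation-based significance testing,
    Bonferroni correction and Haufe-transformed activation patterns; and
    computes Lempel-Ziv (LZ76) complexity of binarized epochs as an
    alternative feature family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    minpack.lm,
    pROC
Config/testthat/edition: 3
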