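Package: rsacoupling
Title: Linear and Nonlinear Quantification of Respiratory Sinus Arrhythmia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the linear and nonlinear components of respiratory
    sinus arrhythmia (RSA) from paired respiration and heart-rate-variability
    (HRV) recordings. Present HRV samples are predicted from past respiration
    with epsilon-support-vector regression under a linear and a radial basis
    function kernel, yielding the explained-variance indices Pxl and Pxk;
    these are compared against Px, the reference linear estimate obtained by
    orthogonal subspace projection of the HRV onto a lagged-respiration
    subspace. Nonlinearity of the coupling is assessed with multivariate
    amplitude-adjusted phase-randomized surrogate data. Includes the standard
    2 Hz tachogram preprocessing chain (RR interpolation, band-pass
    filtering, 5-minute epoching, Welch spectra), spectral model-order
    selection, a coupled autoregressive simulator with controllable linear
    and quadratic interaction strength, a synthetic cardiorespiratory epoch
    generator, and nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
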