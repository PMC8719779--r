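Package: beadcal
Title: Thermal-Motion Force Calibration for Single-Molecule Video-Tracking
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates forces in magnetic- and optical-tweezers experiments
    that track a trapped bead by video. Estimates the bead drag coefficient
    and trap spring constant (and, optionally, the camera tracking error)
    with uncertainties from a single bead trajectory, by maximum-likelihood
    fits of the Welch power spectral density or the overlapping Allan
    variance to closed-form thermal-motion models that correct for camera
    exposure blur and aliasing. Includes an exact overdamped-Langevin
    simulator with exposure averaging, Gamma-likelihood inference with
    Hessian and ensemble-MCMC uncertainties, per-point equivalent degrees of
    freedom via power-law noise identification, and fit diagnostics
    (reduced chi-squared, support, AIC model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
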