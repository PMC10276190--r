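Package: specslope
Title: Wide-Band Aperiodic (1/f) Slope Analysis for EEG Power Spectra
Version: 0.1.0
Authors@R:
    person("specslope", "authors", email = "specslope@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the aperiodic (1/f) component of EEG
    power spectral densities over a wide frequency range (4-1000 Hz):
    artifact rejection for eyes-open and eyes-closed recordings,
    trial-averaged single-taper multitaper PSD estimation, iterative
    aperiodic + periodic (Gaussian peak) spectral model fitting, direct
    log-log line fits, sliding-window and fixed-band slope profiling with
    line-noise avoidance, and nonparametric group statistics (rank tests,
    run-length cluster correction, Benjamini-Hochberg FDR, bootstrap
    standard error of the median, case-control matching). Includes a
    synthetic multichannel EEG cohort generator with configurable
    age-dependent spectral exponents, oscillatory peaks, line noise and
    injected artifacts, so the whole pipeline is testable end to end
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
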