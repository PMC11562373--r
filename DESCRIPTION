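Package: ringdeconv
Title: Ring-Polymer Spectra by Toeplitz Deconvolution and Path-Integral Weight Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for path-integral and ring-polymer molecular dynamics of
    small model systems. Solves the path-integral weight-function functional
    equation as a banded triangular Toeplitz system on a squared-frequency
    grid (with an extended-precision backend), simulates PIMD/RPMD
    trajectories for harmonic, Morse and triatomic water models with a PILE
    thermostat, computes velocity autocorrelation functions and vibrational
    densities of states, and recovers physical and quantum-corrected spectra
    from bead-level spectra by bounded non-negative deconvolution of the
    ring-polymer convolution operator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
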