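Package: dualprobe
Title: Dual-Probe Rinse-Kinetics Estimation of Receptor Binding Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental kinetic modeling of paired targeted and untargeted
    nanoparticle probes applied topically to tissue and removed by serial
    rinsing, for the estimation of cell-surface receptor binding potential
    (BP = k3/k4). Provides forward simulators for the two-compartment
    (dual-probe model, DPM) and three-compartment (DPM with nonspecific
    binding, DPM-NS) linear systems, three BP estimators (ratiometric,
    DPM, DPM-NS) fitted by separable non-negative least squares with a
    randomized column Kaczmarz-Tikhonov solver for the exponential-basis
    amplitudes, direct classical least squares (DCLS) spectral
    demultiplexing of Raman-style fingerprint spectra with concentration
    calibration, Monte-Carlo precision and bias studies of the estimators
    under nonspecific binding, and SPSS-style one-way ANOVA group
    comparisons with Levene-gated post-hoc tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    car,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
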