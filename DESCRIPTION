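Package: cardiowave
Title: Spiral-Wave Dynamics in the Modified Luo-Rudy 1991 Ventricular Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-cell, cable and two-dimensional monodomain simulation of
    the 1991 Luo-Rudy guinea-pig ventricular action-potential model extended
    with the Mahajan fast transient-outward potassium current (Ito,f) and
    multiplicative scale factors on the L-type calcium gate time constants.
    Provides pacing, S1S2 restitution and cross-field spiral-induction
    protocols; action-potential duration, alternans and spike-and-dome
    morphology analysis; phase-singularity detection and spiral-wave dynamics
    classification; parameter sweeps for breakup phase diagrams; and
    unipolar/bipolar pseudo-ECG computation from tissue voltage fields.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
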