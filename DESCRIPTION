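Package: avfppg
Title: Photoplethysmography-Based Assessment of Arteriovenous Fistula
    Stenosis and Blood Flow
Version: 0.1.0
Authors@R: person("AVF", "PPG Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for screening arteriovenous fistulas of hemodialysis
    patients from photoplethysmography (PPG) measurements. Implements a
    hemodynamic forward model linking vessel stenosis and blood-flow volume
    to perfusion-index features through Beer-Lambert optics and a
    telegrapher-equation (transmission-line) description of pulsatile flow
    with Womersley corrections; a software emulation of an adaptive
    band-pass readout chain that extracts perfusion indices and heart rate
    from raw waveforms; k-nearest-neighbour, Gaussian naive Bayes and
    RBF support-vector-machine classifiers with nested grid search and
    stratified 10-fold cross-validation; and a seeded synthetic cohort and
    waveform generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
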