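Package: stnforce
Title: Decoding Gripping Force from Subthalamic Nucleus Local Field Potentials
Version: 0.1.0
Authors@R: person("STN", "Decoding Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to decode the temporal profile of isometric gripping force
    from band-power features of subthalamic-nucleus local field potentials
    (LFPs) recorded through deep-brain-stimulation electrodes. The package
    derives bipolar channels, extracts movement-related power changes in the
    theta/alpha (4-12 Hz), beta (13-30 Hz) and gamma (55-90 Hz) bands with a
    7-cycle Morlet continuous wavelet transform, fits a family of eight
    first-order linear dynamic models with dead time by bounded multi-start
    least squares, and evaluates decoders with effort-split and k-fold
    cross-validation, per-trial correlation and error metrics, and BIC model
    comparison. A fully parameterised synthetic-session generator (band-limited
    oscillatory carriers with effort-scaled power modulation over 1/f
    background, force produced by a known transfer function) makes every stage
    testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
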