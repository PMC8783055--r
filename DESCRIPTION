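Package: fretpath
Title: Kinetic Analysis of Single-Molecule FRET Trajectories of
    Transcription Open-Complex Formation
Version: 0.1.0
Authors@R:
    person("Sam", "Keller", email = "sam.keller@example.org", role = c("aut", "cre"))
Description: Tools to resolve branched kinetic pathways of bacterial RNA
    polymerase open-complex (RPo) formation from single-molecule FRET
    trajectories. Provides a ground-truth trajectory simulator with
    Gaussian-noise FRET emission and exponential state dwells, Gaussian-
    emission hidden Markov model fitting and Viterbi decoding, Allan-
    deviation based transition filtering, static/dynamic and mechanism
    classification, dwell-time exponential kinetics with bootstrap and
    exact binomial confidence intervals, FRET-efficiency histogram
    Gaussian fitting, and simulation-based detection-efficiency
    calibration with missed-event histogram correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
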