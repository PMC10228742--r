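Package: pacpredict
Title: Phase-Amplitude Coupling Features for EEG Seizure Prediction
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sliding-window analysis of long multichannel scalp EEG for
    interictal-versus-preictal classification. Implements the Tort
    modulation index (Kullback-Leibler distance of the phase-binned
    high-frequency amplitude distribution from uniform) over canonical
    band pairs, Welch peak/median frequency per band, seizure-aware state
    labelling with a configurable seizure prediction horizon (SPH),
    grouped k-fold random-forest classification, and an SPH sweep with a
    Kruskal-Wallis comparison. Ships a synthetic-EEG generator with
    controllable, state-dependent phase-amplitude coupling plus a minimal
    EDF reader/writer so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
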