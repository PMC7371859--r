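Package: entrainr
Title: Entrainment Analysis for Rhythmic TMS-EEG Experiments
Version: 0.1.0
Authors@R: person("entrainr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying neural entrainment of posterior alpha
    oscillations by weak rhythmic repetitive transcranial magnetic
    stimulation (rTMS) with simultaneous EEG. Provides stimulation protocol
    generation (rhythmic, arrhythmic with forbidden-frequency constraints,
    sham), electric-field dose helpers, a ground-truth synthetic TMS-EEG
    generator, the full TMS artifact-removal cascade (ringing excision,
    decay-component ICA, shape-preserving gap interpolation, re-referencing,
    downsampling, statistical channel/trial rejection, ocular ICA),
    individual alpha frequency estimation via multitaper spectra,
    phase-locking-value (PLV) entrainment quantification against a simulated
    reference wave, and cluster-based permutation inference over electrodes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
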