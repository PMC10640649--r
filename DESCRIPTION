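Package: peroxHMM
Title: Hidden Markov Segmentation of Organelle Tracks into Random and
    Directed Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments two-dimensional single-particle tracks (for example
    peroxisomes imaged by spinning-disc microscopy and tracked with
    TrackMate) into a slow random-migration state and a fast
    microtubule-directed state using a two-state hidden Markov model on
    per-step dimensionless speed and relative turning angle.  Provides
    scaled Baum-Welch fitting with freezable parameter groups, Viterbi
    decoding, an Ornstein-Uhlenbeck switching-track simulator with ground
    truth states, ensemble mean squared displacement analysis with
    anomalous-exponent fitting, validation metrics, consecutive-run
    statistics with bootstrap confidence intervals, and per-cell condition
    comparison with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
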