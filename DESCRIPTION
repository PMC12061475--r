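Package: striatumrl
Title: Opponent-Pathway Striatal Reinforcement Learning Models and Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis procedures for reinforcement learning in
    dorsal striatum with opponent direct- and indirect-pathway spiny projection
    neurons (dSPNs/iSPNs). Implements dopamine-dependent three-factor plasticity
    rules, softmax action selection with a no-action option, the canonical and
    efference models of post-selection SPN activity, TD and off-policy Q
    critics, a continuous-time firing-rate model of a two-alternative
    forced-choice task with Ornstein-Uhlenbeck noise, spontaneous-behavior
    simulations with Gaussian-process feedforward input, neural-session
    analyses (cross-correlation asymmetry, behavioral-syllable activity-mode
    regression, time-warped onset-aligned projections, selectivity), four
    models relating per-syllable dopamine to syllable transition statistics,
    and synthetic-data generators with known ground truth for testing every
    analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
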