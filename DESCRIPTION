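Package: colseq
Title: Columnar Spiking-Network Simulator for Reward-Gated Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for a modular cortical-column network that
    learns the order and duration of stimulus sequences from a global
    reward/novelty signal. Each column pairs Timer and Messenger excitatory
    populations with layer-specific inhibition; plastic recurrent Timer
    synapses encode element duration and plastic feedforward Messenger
    projections encode transitions, both driven by two competing (LTP/LTD)
    eligibility traces gated by a thresholded Hebbian rate term and consumed
    during 25 ms reward windows. Provides the baseline, all-to-all,
    local-inhibition and size-scaled architecture variants, the full
    training/cued-recall protocol, and the measurement procedures (recall
    times, deviation and modified z-score outliers, ISI coefficient of
    variation, weight trajectories, parameter sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
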