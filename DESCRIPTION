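Package: engramsim
Title: Spiking Network Simulation of Systems Memory Consolidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Seeded, configurable simulator for multi-region spiking
    recurrent networks of systems memory consolidation. Implements
    conductance-based leaky integrate-and-fire neurons with adaptive
    thresholds and spike-triggered adaptation, short-term plasticity,
    triplet spike-timing-dependent plasticity combined with
    heterosynaptic and transmitter-induced plasticity, slow bistable
    synaptic consolidation of reference weights, and network
    activity-based inhibitory plasticity. Provides network presets for
    hippocampal-thalamic-cortical circuits, multi-phase stimulation
    protocols (burn-in, training, consolidation, testing) with
    perturbations (blocking engram output, blocking inhibition, region
    ablation, plasticity knockouts), and analysis tools for engram cell
    labeling, recall metrics with bootstrap intervals, population
    activity, cross-region reactivation coupling, and ensemble weight
    summaries. The simulation kernel is written in C++ for speed; a
    pure-R scalar reference engine with identical semantics backs the
    correctness tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
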