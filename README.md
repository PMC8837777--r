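# engramsim

Spiking network simulation of systems memory consolidation: how memory
representations (engrams) reorganize across a hippocampal–thalamic–cortical
circuit after learning.

`engramsim` is for computational neuroscientists who want a seeded,
configurable, desk-scale implementation of the multi-region consolidation
model in which four interacting plasticity mechanisms — triplet
spike-timing-dependent plasticity, heterosynaptic plasticity,
transmitter-induced plasticity, and slow bistable synaptic consolidation —
together with network-activity-based inhibitory plasticity produce
region-specific engram dynamics: hippocampal engram cells form in an
active state and turn silent over consolidation (de-maturation), cortical
engram cells form silent and become active (maturation), and spontaneous
engram reactivations couple across regions through a subcortical relay.

## The model in brief

Leaky integrate-and-fire neurons with conductance-based synapses and an
adaptive threshold:

    tau_m dU/dt = (U_rest - U) + g_exc (U_exc - U) + (g_gaba + g_a)(U_inh - U)

Excitatory long-term plasticity per synapse `w_ij` (pre j, post i):

    dw/dt =  eta * ( A z+_j z_slow_i S_i  -  B_i z-_i S_j )     # triplet STDP
           -  beta (w - w~) (z-_i)^3 S_i                        # heterosynaptic
           +  delta S_j                                          # transmitter-induced

with the LTD rate `B_i = A min(C_i, 1)` homeostatically regulated, and
reference weights `w~` following the negative gradient of a double-well
potential on a slow timescale `tau_cons` (synaptic consolidation).
Inhibitory I→E synapses follow a network-activity-gated STDP rule that
steers each region's excitatory rate to a target. Regions differ only in
learning rates and consolidation timescales — subcortical regions learn
fast but their sensory afferents consolidate slowly, cortex learns slowly
but consolidates fast — and that ordering alone produces the opposite
recall trajectories of HPC and CTX.

The per-step kernel is C++ (Rcpp); a pure-R scalar reference engine with
identical update semantics backs the correctness tests.

## Worked example

Train the desk-scale two-region network (512 excitatory / 128 inhibitory
neurons per region, 1024 stimulus cells) on four non-overlapping random
stimuli and probe recall with 50% partial cues immediately after
training:

```r
library(engramsim)

spec     <- network_preset("two-region", scale = "desk", seed = 1)
net      <- build_network(spec)
stimuli  <- make_stimuli("random-nonoverlapping", spec$N_stim, 4,
                         seed = seed_stream(1, "stimuli"))
schedule <- protocol_preset("two-region", scale = "desk",
                            T_consolidation = 0, test_times = 0)
run      <- run_protocol(net, stimuli, schedule, seed = 1)
run_recall_table(run)
#>   region time accuracy tpr fpr n_cues
#> 1    HPC    0      0.5 0.5   0      8
#> 2    CTX    0      0.5 0.5   0      8
```

Each row is one readout region at consolidation time zero: half of the
eight partial cues reactivate the matching engram ensemble, and no cue
ever activates a wrong ensemble (f.p.r. 0). Desk-scale recall metrics are
deliberately small-sample (eight cues per test) and move by a cue or two
across seeds; across five seeded trials the time-zero true positive rates
average about 0.66 (HPC) and 0.59 (CTX). The learned structure behind the
recall is one call away:

```r
ks <- ensemble_weight_ks(snapshot_weights(net, "HPC:EE"),
                         run$labels$exc$HPC)
c(mean(ks$within), mean(ks$between), ks$p_value)
#> [1] 0.991 0.713 0.000
```

Within-ensemble recurrent weights (0.99) clearly exceed inter-ensemble
weights (0.71) — the block-diagonal engram structure — and the
Kolmogorov-Smirnov comparison between the two synapse-weight
distributions rejects at any conventional level.

A command-line entry point wraps the same pipeline:

```
inst/cli/engramsim run --preset three-region --scale desk --seed 1 --out run1
inst/cli/engramsim report --out run1
```

## Package layout

* `R/core-dynamics.R`, `R/plasticity.R` — single-step operations defining
  the model semantics (documented, unit-tested against closed forms)
* `src/engine.cpp` — the compiled network kernel
* `R/reference-engine.R` — pure-R scalar engine, the correctness oracle
* `R/network.R`, `R/presets.R` — network specs, presets, receptive fields
* `R/protocol.R` — stimuli, schedules, phases, manipulations
* `R/analysis.R` — engram labeling, recall metrics, coupling, statistics
* `R/io.R`, `R/cli.R` — configs, event/weight serialization, manifests, CLI
* `vignettes/consolidation-model.Rmd` — model equations, numerics, and the
  desk-scale design decisions
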