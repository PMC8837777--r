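---
title: "Model and methods: multi-region spiking networks of systems consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multi-region spiking networks of systems consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`engramsim` simulates systems memory consolidation: the time-dependent
reorganization of memory representations (engrams) across brain regions.
A stimulus population drives two or three recurrently connected regions —
a hippocampus-like region (HPC) with fast plasticity and slow synaptic
consolidation of its sensory afferents, a cortex-like region (CTX) with
slow plasticity and fast consolidation, and optionally a thalamus-like
relay (THL) between them. After training on a set of stimuli, the network
evolves spontaneously; engram ensembles reactivate, feedforward synapses
onto HPC engram cells depress while the cortical afferent pathway
potentiates, and recall probed with partial cues migrates from HPC to CTX.
This vignette documents the model equations, the numerical scheme, the
desk-scale study conditions used by the test and acceptance suites, and
the design decisions taken where the design was genuinely open.

## Neuron and synapse model

Neurons are conductance-based leaky integrate-and-fire units with an
adaptive threshold and spike-triggered adaptation:

$$\tau^m \dot U_i = (U^{rest} - U_i) + g^{exc}_i(t)\,(U^{exc} - U_i) +
  \left(g^{gaba}_i(t) + g^a_i(t)\right)(U^{inh} - U_i)$$

A spike is fired when $U_i > \vartheta_i$; the membrane resets to
$U^{rest}$ and the threshold jumps to $\vartheta^{spike}$, decaying back to
$\vartheta^{rest}$ with $\tau^{thr}$ (this doubles as a soft refractory
mechanism). Conductances are dimensionless multiples of the leak
conductance. Excitatory input mixes a fast AMPA-like and a slow NMDA-like
component, $g^{exc} = \alpha\, g^{ampa} + (1-\alpha)\, g^{nmda}$, with
$g^{nmda}$ a first-order low-pass of $g^{ampa}$. Presynaptic spikes
increment $g^{ampa}$ by $w_{ij}\, u_j x_j$ (excitatory) or $g^{gaba}$ by
$w_{ij}$ (inhibitory); $u_j, x_j$ are the per-presynaptic-neuron
short-term facilitation/depression variables with jump rule
"facilitate `u` first, then depress `x` with the updated `u`", while the
transmitted efficacy uses the pre-jump product. Defaults (all exposed in
`neuron_params()` / `stp_params()`): $\tau^m = 20$ ms, $U^{rest} = -70$ mV,
$U^{exc} = 0$ mV, $U^{inh} = -80$ mV, $\vartheta^{rest} = -50$ mV,
$\vartheta^{spike} = 50$ mV, $\tau^{thr} = 5$ ms, $\alpha = 0.3$,
$\tau^{ampa} = 5$ ms, $\tau^{nmda} = 100$ ms, $\tau^{gaba} = 10$ ms,
$\tau^{a} = 500$ ms, $\Delta^a = 0.08$. These constants follow the
conventions of earlier single-region spiking models of memory formation
with this architecture; none of them is sensitive in isolation, and all
are configurable.

## Plasticity

Four mechanisms act simultaneously and are all active in every phase:

1. **Triplet STDP** (Hebbian): potentiation per postsynaptic spike
   $\eta\, A\, z^+_j z^{slow}_i(t-\epsilon)$, depression per presynaptic
   spike $\eta\, B_i z^-_i$ with the homeostatically regulated LTD rate
   $B_i = A \min(C_i, 1)$, $\dot C_i = -C_i/\tau^{hom} + (z^{ht}_i)^2$.
2. **Heterosynaptic plasticity**: per postsynaptic spike every afferent
   synapse is pulled toward its reference weight,
   $-\beta\,(w_{ij} - \tilde w_{ij})\,(z^-_i(t-\epsilon))^3$. The cubic
   gate makes this a burst detector: it is negligible at background rates
   and dominant during high-rate events, anchoring weights to
   $\tilde w$ and providing the synaptic competition that stops runaway
   potentiation.
3. **Transmitter-induced plasticity**: $+\delta$ per presynaptic spike, a
   small unconditional drive that maintains network excitability and sets
   the rate of spontaneous reactivations.
4. **Inhibitory plasticity** on I→E synapses, gated by the difference
   between a region-wide low-pass of excitatory spiking $H(t)$ and a
   target $\gamma$: it potentiates inhibition when the region runs above
   target and depresses it below, steering the mean excitatory rate.

Reference weights evolve on a slow timescale as the negative gradient of a
double-well potential (step $\Delta_{long} = 1.2$ s),
$$\tau^{cons}\dot{\tilde w} = w - \tilde w - P\,\tilde w\,(w^P/2 -
\tilde w)(w^P - \tilde w),$$
with $P = 20$, $w^P = 0.5$: a synapse whose weight is held well above its
reference crosses the potential barrier and consolidates; otherwise
$\tilde w$ relaxes back. The *ordering* of consolidation timescales is
what drives the region-specific engram dynamics: the sensory afferents of
HPC consolidate much more slowly than every other plastic projection, so
hippocampal feedforward potentiation remains anchored near its baseline
and is eroded by heterosynaptic pulls during reactivations
(de-maturation), while cortical afferents consolidate quickly and retain
the potentiation accumulated during coupled reactivations (maturation).

`t - eps` semantics: every rule evaluation triggered by a spike reads
trace values after that step's decay but before the spike's own
increment. Weight bounds are enforced after every discrete update.

## Update order and numerics

One time step ($\Delta = 0.1$ ms, forward Euler) proceeds as: (1)
conductance decay and delivery of the previous step's weighted spikes
(one-step synaptic delay convention), with the NMDA low-pass reading the
post-update AMPA value; (2) membrane and threshold integration; (3) spike
detection and reset; (4) trace/STP/homeostasis decays (traces use the
exact per-step exponential factor — they are linear, so this is exact and
stabler than Euler; membrane and conductances remain forward Euler),
rule evaluation (presynaptic-spike rules then postsynaptic-spike rules,
projection by projection), transmission queuing, then trace increments;
(5) every $\Delta_{long}$, an Euler step of the reference weights. The
compiled kernel flushes subnormal floating-point values to zero every 256
steps; purely decaying conductances otherwise linger in the denormal
range where hardware arithmetic is dramatically slower (the flush changes
state by less than 1e-30 and is invisible at the 1e-10 comparison
tolerance of the kernel-equivalence tests).

A pure-R scalar reference engine (`reference_engine()`), composed from
the exported single-step operations, implements the same order and is
compared step-for-step with the compiled kernel on micro networks; this
is the package's primary correctness argument.

## Network configurations

Each region has $N_{exc}$ excitatory and $N_{inh}$ inhibitory neurons
(4:1), recurrently connected with probability $\epsilon_{rec}$, with fixed
plasticity roles: E→E recurrent synapses carry short- plus long-term
plasticity, E→I only short-term plasticity, I→E inhibitory plasticity,
I→I static. Inter-region projections originate from excitatory cells
only. The two-region configuration feeds HPC and CTX independently from a
stimulus population (no HPC–CTX connection); the three-region
configuration routes STIM → HPC → THL → CTX with circular receptive
fields from the stimulus grid into HPC (plastic) and THL (static, the
relay's receptive fields being treated as developmentally fixed), and two
external Poisson populations that drive HPC and CTX only during
consolidation (the stimulus population is silent then). Presets exist for
the variant configurations (direct HPC→CTX plastic/static/bidirectional,
a shared downstream readout region, and a two-cortical-region reentrant
extension).

## Desk scale: the study conditions of the test suites

The full-scale system (4096 excitatory neurons per region, 12–24 h of
simulated consolidation) is cluster-sized. The package's standard
configuration — the `"desk"` scale returned by `network_preset()` and
`protocol_preset()` — keeps the architecture and the 4:1 E/I ratio but
uses 512/128 neurons per region, a 1024-cell stimulus grid (32×32),
minutes-long phases, and plasticity rates scaled up so that the slow
processes (consolidation of reference weights, maturation of the cortical
pathway) complete within minutes instead of hours. The guiding
constraints, in the package's own calibration:

* the consolidation time constant of ordinary plastic projections sits
  below the training duration, so that the recurrent structure and the
  cortical afferents acquired in training cross the double-well barrier
  and are anchored before the spontaneous phase begins (training shorter
  than the consolidation timescale leaves every learned weight un-anchored
  and the heterosynaptic pull erases it during consolidation);
* the STIM→HPC consolidation time constant must exceed the whole
  simulated period, so hippocampal feedforward potentiation is never
  consolidated;
* subcortical learning rates exceed cortical ones (here 4:1), with
  transmitter-induced rates scaled in proportion;
* the short-term-depression recovery time is shortened (to 50 ms) so
  that a strong stimulus rate contrast survives synaptic depression at
  the reduced in-degrees of the small network;
* the background/stimulus firing-rate contrast is larger than at full
  scale (2 Hz vs 75 Hz during training), because stimulus selectivity at
  512 neurons per region rests on far fewer afferent samples.

These are choices of the package, stated here once; the presets are the
single source of those values, every one of which can be overridden
through `network_spec()` / `protocol_schedule()`.

What the desk scale reproduces: engram formation with block-diagonal
recurrent structure, hippocampal recall that is high immediately after
training and collapses over consolidation, initially partial cortical
recall, opposite drift of the feedforward weight totals onto HPC versus
CTX engram cells, spontaneous ensemble reactivations during consolidation
and their coupling (three-region) or decoupling (two-region) across
regions, and the dependence of cortical maturation on subcortical engram
output. What it does not reproduce: the absolute timescales (minutes
stand in for a day), exact full-scale recall percentages at late time
points, oscillatory structure (no LFPs are modelled), and the
slow-timescale statistics of very long consolidation periods.

## Analyses

Engram cells are labeled by their mean stimulus-evoked rate over the
final stretch of training exceeding $\zeta^{thr} = 10$ Hz; an ensemble is
"activated" by a cue if its mean population rate over the full cue-on
window exceeds the same threshold (the window-mean is the package's
reading of "during cue presentation"; it is robust to bin noise). Recall
true/false positive rates and accuracy follow directly; the false
positive rate averages over the $k - 1$ non-cued ensembles. Population
activity uses plain 10 ms bins without smoothing. Cross-region
reactivation coupling is summarized by the lag maximizing the Pearson
cross-correlogram of two mean-subtracted ensemble rate series, ties
broken toward the smallest absolute lag, positive lags meaning the first
series leads. Bootstrap intervals for recall metrics use the percentile
method with 10,000 seeded resamples. Two-sample comparisons route the
conventional way: Kolmogorov–Smirnov for weight distributions,
Mann–Whitney for recall metrics, and for activation percentages an
unpaired or Welch t-test when Shapiro–Wilk (0.05) accepts normality with
Levene (0.05) deciding the variance question, Mann–Whitney otherwise.

## Degenerate inputs, tie-breaks, tolerances

Empty ensembles never count as activated and are skipped (with a warning)
in recall tables; labeling errors out if a stimulus has no presentation
inside the labeling window; `lag_max()` rejects zero-variance series; the
reference-weight step aborts with a diagnostic naming the
$\tau^{cons}/\Delta_{long}$ ratio if an unstable parameter combination
makes $\tilde w$ diverge. Poisson drive rejects `rate * dt >= 1`.
Connectivity, stimulus draws, event schedules, engine drive and bootstrap
resampling all derive from a single master seed through named streams
(`seed_stream()`), so any one component's draws can change without
perturbing the others, and every run is reproducible from its manifest.

## Problem sizes used by the suites

The unit and property suites run on micro fixtures (6 excitatory + 2
inhibitory neurons per region, 12 stimulus cells, below one second of
simulated time). The acceptance suite and `scripts/acceptance.R` run the
desk-scale presets: training of a few hundred seconds, consolidation
recordings of up to 1800 s, and small numbers of seeded trials (3–5) for
the trial-level comparisons. These sizes are the package's standard desk
configuration; larger runs only require changing the preset scale.

## Known limitations

Point neurons without conduction delays beyond the one-step convention;
no oscillation/LFP modelling; per-presynaptic-neuron (not per-synapse)
short-term plasticity; desk-scale recall percentages are noisier than the
full-scale model's and sit closer to the activation threshold, so
individual trials can deviate substantially from trial means; and the
compressed timescales mean that desk-scale "hours" claims are read as
direction-of-change claims, not absolute-time claims.
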