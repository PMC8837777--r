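# shared helpers for the test suite; everything is generated in code

micro_net <- function(seed = 3) {
  fx <- make_fixture("micro", seed = seed)
  build_network(fx$spec)
}

# deterministic dense-ish Bernoulli spike schedule for a fixed-drive pop:
# returns list(spike_step, spike_id) with unique ids per step
fixed_drive <- function(nsteps, n, p, seed = 42) {
  set.seed(seed)
  steps <- integer(0); ids <- integer(0)
  for (s in seq_len(nsteps)) {
    sp <- which(runif(n) < p)
    steps <- c(steps, rep(s, length(sp)))
    ids <- c(ids, sp)
  }
  list(spike_step = steps, spike_id = ids)
}

# raster constructor: neuron fires at a given rate within [t0, t1]
regular_spikes <- function(neuron, rate, t0, t1) {
  if (rate <= 0) return(data.frame(time = numeric(0), neuron = integer(0)))
  times <- seq(t0 + 1 / rate / 2, t1, by = 1 / rate)
  data.frame(time = times, neuron = rep(neuron, length(times)))
}
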