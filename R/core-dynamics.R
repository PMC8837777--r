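#' Per-region neuronal state
#'
#' Holds the dynamical variables of one population: membrane voltage,
#' firing threshold, and the four conductances (AMPA-like, NMDA-like,
#' GABA, spike-triggered adaptation). Conductances are dimensionless
#' multiples of the leak conductance and must stay nonnegative.
#'
#' @param n neuron count
#' @param params a [neuron_params()] object supplying resting values
#' @return an object of class `region_state`
#' @export
region_state <- function(n, params = neuron_params()) {
  stopifnot(n >= 1)
  structure(list(
    n = as.integer(n),
    U = rep(params$U_rest, n),
    theta = rep(params$theta_rest, n),
    g_ampa = numeric(n), g_nmda = numeric(n),
    g_gaba = numeric(n), g_a = numeric(n)
  ), class = "region_state")
}

check_region_state <- function(state) {
  lens <- vapply(state[c("U", "theta", "g_ampa", "g_nmda", "g_gaba", "g_a")],
                 length, integer(1))
  if (length(unique(lens)) != 1L || lens[[1]] != state$n)
    stop("region_state: vector lengths differ from neuron count")
  invisible(state)
}

#' One forward-Euler step of the membrane and threshold dynamics
#'
#' Advances `U` by one Euler step of the conductance-based membrane
#' equation and `theta` by one Euler step of its exponential decay towards
#' `theta_rest`. The excitatory conductance is computed as
#' `alpha * g_ampa + (1 - alpha) * g_nmda`. No spike detection happens
#' here; call [detect_spikes_and_reset()] afterwards.
#'
#' @param state a [region_state()] object
#' @param params a [neuron_params()] object
#' @param dt time step \[s\], must be positive
#' @return the updated `region_state`
#' @export
integrate_membrane <- function(state, params, dt) {
  stopifnot(dt > 0)
  bad <- which(!is.finite(state$U) | !is.finite(state$theta))
  if (length(bad))
    stop("integrate_membrane: non-finite state at neuron index ", bad[1])
  g_exc <- params$alpha * state$g_ampa + (1 - params$alpha) * state$g_nmda
  dU <- ((params$U_rest - state$U) +
           g_exc * (params$U_exc - state$U) +
           (state$g_gaba + state$g_a) * (params$U_inh - state$U)) / params$tau_m
  state$U <- state$U + dt * dU
  state$theta <- state$theta + dt * (params$theta_rest - state$theta) / params$tau_thr
  state
}

#' Detect threshold crossings and reset the spiking neurons
#'
#' Every neuron with `U > theta` emits a spike: its membrane is reset to
#' `U_rest` and its threshold jumps to `theta_spike`. Returns the spiking
#' indices; the state is modified in the returned object.
#'
#' @inheritParams integrate_membrane
#' @return a list with `spikes` (integer indices) and `state`
#' @export
detect_spikes_and_reset <- function(state, params) {
  spikes <- which(state$U > state$theta)
  if (length(spikes)) {
    state$U[spikes] <- params$U_rest
    state$theta[spikes] <- params$theta_spike
  }
  list(spikes = spikes, state = state)
}

#' Decay conductances and deliver this step's synaptic input
#'
#' Applies one step of conductance dynamics: each conductance decays with
#' its time constant (forward Euler by default, exact exponential decay
#' optionally), then increments are delivered. `exc_input` must already
#' include the short-term-plasticity factors `u_j * x_j` for each
#' presynaptic spike; `inh_input` carries plain weights (signs live in the
#' reversal potentials, so both inputs are nonnegative magnitudes). The
#' NMDA-like conductance is a low-pass filter of the AMPA-like conductance
#' and is updated from the post-update AMPA value. The adaptation
#' conductance increments by `Delta_a` for each spike of the neuron itself.
#'
#' @inheritParams integrate_membrane
#' @param exc_input per-neuron weighted excitatory spike sum (nonnegative)
#' @param inh_input per-neuron weighted inhibitory spike sum (nonnegative)
#' @param own_spikes integer indices of this population's spikes being
#'   delivered this step
#' @param exact use exact exponential decay factors instead of forward
#'   Euler (default `FALSE`)
#' @return the updated `region_state`
#' @export
decay_and_deliver_conductances <- function(state, params, exc_input = 0,
                                           inh_input = 0,
                                           own_spikes = integer(0), dt,
                                           exact = FALSE) {
  stopifnot(dt > 0)
  if (any(exc_input < 0) || any(inh_input < 0))
    stop("decay_and_deliver_conductances: input sums must be nonnegative; ",
         "weights are magnitudes and the sign is carried by reversal potentials")
  dec <- function(tau) if (exact) exp(-dt / tau) else 1 - dt / tau
  state$g_ampa <- state$g_ampa * dec(params$tau_ampa) + exc_input
  state$g_gaba <- state$g_gaba * dec(params$tau_gaba) + inh_input
  state$g_a <- state$g_a * dec(params$tau_a)
  if (length(own_spikes)) {
    cnt <- tabulate(own_spikes, nbins = state$n)
    state$g_a <- state$g_a + params$Delta_a * cnt
  }
  state$g_nmda <- state$g_nmda +
    dt / params$tau_nmda * (state$g_ampa - state$g_nmda)
  state
}
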