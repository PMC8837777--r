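#' Neuron parameters
#'
#' Parameters of the conductance-based leaky integrate-and-fire neuron with
#' an adaptive firing threshold and spike-triggered adaptation. The membrane
#' obeys
#' \deqn{\tau^m \dot U_i = (U^{rest}-U_i) + g^{exc}_i (U^{exc}-U_i) +
#'   (g^{gaba}_i + g^a_i)(U^{inh}-U_i)}
#' with the excitatory conductance a fixed mixture of a fast (AMPA-like) and
#' a slow (NMDA-like) component, \eqn{g^{exc} = \alpha g^{ampa} +
#' (1-\alpha) g^{nmda}}. A neuron fires when \eqn{U_i > \vartheta_i}; its
#' membrane is then reset to `U_rest` and the threshold jumps to
#' `theta_spike`, decaying back to `theta_rest` with time constant
#' `tau_thr`.
#'
#' All time constants are in seconds, voltages in mV. Conductances are
#' dimensionless multiples of the leak conductance, as implied by the form
#' of the membrane equation.
#'
#' @param tau_m membrane time constant \[s\]
#' @param U_rest resting potential \[mV\]
#' @param U_exc excitatory reversal potential \[mV\]
#' @param U_inh inhibitory reversal potential \[mV\]
#' @param theta_rest resting firing threshold \[mV\]
#' @param theta_spike post-spike threshold value \[mV\]
#' @param tau_thr threshold decay time constant \[s\]
#' @param alpha relative AMPA contribution to the excitatory conductance,
#'   in \[0, 1\]
#' @param tau_ampa,tau_nmda,tau_gaba,tau_a conductance time constants \[s\]
#' @param Delta_a adaptation conductance increment per spike (dimensionless)
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(tau_m = 20e-3,
                          U_rest = -70, U_exc = 0, U_inh = -80,
                          theta_rest = -50, theta_spike = 50,
                          tau_thr = 5e-3,
                          alpha = 0.3,
                          tau_ampa = 5e-3, tau_nmda = 100e-3,
                          tau_gaba = 10e-3, tau_a = 0.5,
                          Delta_a = 0.08) {
  p <- list(tau_m = tau_m, U_rest = U_rest, U_exc = U_exc, U_inh = U_inh,
            theta_rest = theta_rest, theta_spike = theta_spike,
            tau_thr = tau_thr, alpha = alpha,
            tau_ampa = tau_ampa, tau_nmda = tau_nmda, tau_gaba = tau_gaba,
            tau_a = tau_a, Delta_a = Delta_a)
  taus <- c(p$tau_m, p$tau_thr, p$tau_ampa, p$tau_nmda, p$tau_gaba, p$tau_a)
  if (any(!is.finite(unlist(p)))) stop("neuron_params: non-finite value")
  if (any(taus <= 0)) stop("neuron_params: all time constants must be > 0")
  if (p$alpha < 0 || p$alpha > 1) stop("neuron_params: alpha must lie in [0, 1]")
  if (!(p$U_inh <= p$U_rest)) stop("neuron_params: requires U_inh <= U_rest")
  if (!(p$U_rest < p$theta_rest)) stop("neuron_params: requires U_rest < theta_rest")
  if (!(p$theta_rest < p$theta_spike)) stop("neuron_params: requires theta_rest < theta_spike")
  if (!(p$U_exc > p$U_rest)) stop("neuron_params: requires U_exc > U_rest")
  structure(p, class = "neuron_params")
}

#' Short-term plasticity parameters
#'
#' Depression/facilitation dynamics of the per-presynaptic-neuron release
#' variables `u` (utilisation) and `x` (resources). Between spikes `x`
#' relaxes towards 1 with `tau_d` and `u` towards `U_stp` with `tau_f`;
#' at a presynaptic spike `u` facilitates by `U_stp * (1 - u)` and `x` is
#' then depressed by `u * x` (with the facilitated `u`). The transmitted
#' efficacy factor is the product `u * x` evaluated just before the jumps.
#'
#' @param U_stp initial release probability, in (0, 1\]
#' @param tau_d depression (resource recovery) time constant \[s\]
#' @param tau_f facilitation time constant \[s\]
#' @export
stp_params <- function(U_stp = 0.2, tau_d = 0.2, tau_f = 0.6) {
  if (U_stp <= 0 || U_stp > 1) stop("stp_params: U_stp must be in (0, 1]")
  if (tau_d <= 0 || tau_f <= 0) stop("stp_params: time constants must be > 0")
  structure(list(U_stp = U_stp, tau_d = tau_d, tau_f = tau_f),
            class = "stp_params")
}

#' Long-term excitatory plasticity parameters
#'
#' Parameters of the combined triplet STDP + heterosynaptic +
#' transmitter-induced excitatory learning rule with slow bistable
#' consolidation of per-synapse reference weights.
#'
#' The weight update is, per spike event,
#' \deqn{\Delta w_{ij} = \eta^{exc}\left(A z^+_j z^{slow}_i(t-\epsilon) S_i
#'   - B_i z^-_i S_j\right) - \beta (w_{ij}-\tilde w_{ij})
#'   (z^-_i(t-\epsilon))^3 S_i + \delta S_j}
#' where the LTD rate \eqn{B_i = A \min(C_i, 1)} is homeostatically
#' regulated by the squared slow rate trace \eqn{z^{ht}_i} through
#' \eqn{\dot C_i = -C_i/\tau^{hom} + (z^{ht}_i)^2}. Reference weights
#' \eqn{\tilde w} follow the negative gradient of a double-well potential
#' with time constant `tau_cons` (see [consolidate_reference()]).
#'
#' `t - eps` denotes that rule evaluations triggered by a spike read trace
#' values before that spike's own increment.
#'
#' @param eta_exc learning rate (dimensionless)
#' @param A LTP rate
#' @param beta heterosynaptic plasticity strength
#' @param delta transmitter-induced plasticity strength (weight increment
#'   per presynaptic spike, scaled by `eta_exc` not at all: applied as-is)
#' @param tau_plus,tau_minus,tau_slow,tau_ht trace time constants \[s\]
#' @param tau_hom homeostatic integrator time constant \[s\]
#' @param tau_cons reference-weight consolidation time constant \[s\]
#' @param P double-well magnitude
#' @param w_P reference-weight scale of the double-well potential
#' @param w_min_exc,w_max_exc hard weight bounds
#' @export
exc_plasticity_params <- function(eta_exc = 1,
                                  A = 1e-3, beta = 50e-3, delta = 2e-5,
                                  tau_plus = 20e-3, tau_minus = 20e-3,
                                  tau_slow = 100e-3, tau_ht = 100e-3,
                                  tau_hom = 10, tau_cons = 900,
                                  P = 20, w_P = 0.5,
                                  w_min_exc = 0, w_max_exc = 5) {
  p <- list(eta_exc = eta_exc, A = A, beta = beta, delta = delta,
            tau_plus = tau_plus, tau_minus = tau_minus,
            tau_slow = tau_slow, tau_ht = tau_ht,
            tau_hom = tau_hom, tau_cons = tau_cons, P = P, w_P = w_P,
            w_min_exc = w_min_exc, w_max_exc = w_max_exc)
  if (any(c(p$eta_exc, p$A, p$beta, p$delta) < 0))
    stop("exc_plasticity_params: eta_exc, A, beta, delta must be >= 0")
  if (any(c(p$tau_plus, p$tau_minus, p$tau_slow, p$tau_ht,
            p$tau_hom, p$tau_cons) <= 0))
    stop("exc_plasticity_params: all time constants must be > 0")
  if (!(p$w_min_exc < p$w_max_exc))
    stop("exc_plasticity_params: requires w_min_exc < w_max_exc")
  structure(p, class = "exc_plasticity_params")
}

#' Inhibitory plasticity parameters
#'
#' Network activity-based STDP on inhibitory-to-excitatory synapses:
#' \deqn{\dot w_{ij} = \eta^{inh} G(t) [(z_i + 1) S_j + z_j S_i]}
#' with \eqn{G = H - \gamma}, where `H` is a region-wide low-pass filter
#' (time constant `tau_H`) of all excitatory spikes in the region and
#' `gamma` the target activity level (same units as `H`: expected spike
#' count over `tau_H`). Pre- and postsynaptic traces share `tau_istdp`.
#'
#' @param eta_inh learning rate
#' @param gamma target network activity (spikes integrated over `tau_H`)
#' @param tau_H secreted-factor time constant \[s\]
#' @param tau_istdp trace time constant \[s\]
#' @param w_min_inh,w_max_inh weight bounds
#' @export
inh_plasticity_params <- function(eta_inh = 1e-4, gamma = 20,
                                  tau_H = 10, tau_istdp = 20e-3,
                                  w_min_inh = 0, w_max_inh = 10) {
  p <- list(eta_inh = eta_inh, gamma = gamma, tau_H = tau_H,
            tau_istdp = tau_istdp, w_min_inh = w_min_inh,
            w_max_inh = w_max_inh)
  if (p$eta_inh < 0) stop("inh_plasticity_params: eta_inh must be >= 0")
  if (p$tau_H <= 0 || p$tau_istdp <= 0)
    stop("inh_plasticity_params: time constants must be > 0")
  if (!(p$w_min_inh < p$w_max_inh))
    stop("inh_plasticity_params: requires w_min_inh < w_max_inh")
  structure(p, class = "inh_plasticity_params")
}
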