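#' Sparse synaptic projection
#'
#' A source-to-target synapse table with per-synapse weights, optional
#' per-synapse consolidation reference weights, plasticity flags and a
#' per-source blocking mask. Adjacency indices by source and by target are
#' precomputed so that spike-triggered rules can touch exactly the synapses
#' of one neuron.
#'
#' @param n_src,n_tgt population sizes
#' @param src,tgt parallel integer vectors of synapse endpoints (1-based)
#' @param w initial weights (recycled)
#' @param w_tilde reference weights; `NULL` on non-consolidating projections
#' @param plastic_longterm does the projection follow the long-term
#'   excitatory rule?
#' @param plastic_stp does transmission pass through short-term plasticity?
#' @param w_min,w_max hard bounds enforced after every discrete update
#' @return an object of class `sparse_projection`
#' @export
sparse_projection <- function(n_src, n_tgt, src, tgt, w,
                              w_tilde = NULL,
                              plastic_longterm = FALSE, plastic_stp = FALSE,
                              w_min = 0, w_max = Inf) {
  stopifnot(length(src) == length(tgt))
  w <- rep_len(w, length(src))
  if (length(src)) {
    stopifnot(min(src) >= 1, max(src) <= n_src,
              min(tgt) >= 1, max(tgt) <= n_tgt)
  }
  if (!is.null(w_tilde)) {
    w_tilde <- rep_len(w_tilde, length(src))
    if (any(!is.finite(w_tilde))) stop("sparse_projection: w_tilde must be finite")
  }
  fct_src <- factor(src, levels = seq_len(n_src))
  fct_tgt <- factor(tgt, levels = seq_len(n_tgt))
  structure(list(
    n_src = as.integer(n_src), n_tgt = as.integer(n_tgt),
    src = as.integer(src), tgt = as.integer(tgt),
    w = pmin(pmax(w, w_min), w_max), w_tilde = w_tilde,
    plastic_longterm = isTRUE(plastic_longterm),
    plastic_stp = isTRUE(plastic_stp),
    blocked = logical(n_src),
    w_min = w_min, w_max = w_max,
    by_src = split(seq_along(src), fct_src),
    by_tgt = split(seq_along(tgt), fct_tgt)
  ), class = "sparse_projection")
}

clip_w <- function(w, lo, hi) pmin(pmax(w, lo), hi)

#' Short-term plasticity state
#'
#' One `(u, x)` pair per presynaptic neuron, shared across all of that
#' neuron's efferent synapses.
#'
#' @param n presynaptic population size
#' @param params an [stp_params()] object supplying the resting values
#' @export
stp_state <- function(n, params = stp_params()) {
  structure(list(u = rep(params$U_stp, n), x = rep(1, n)),
            class = "stp_state")
}

#' One time step of short-term plasticity
#'
#' Between spikes, `x` relaxes exponentially towards 1 (time constant
#' `tau_d`) and `u` towards `U_stp` (time constant `tau_f`); the relaxation
#' uses the exact exponential factor, exploiting linearity. For each
#' presynaptic neuron spiking this step, `u` then facilitates by
#' `U_stp * (1 - u)` and `x` is depressed by `u * x` using the facilitated
#' `u`. The efficacy factor delivered to postsynaptic conductances is the
#' product `u * x` evaluated after relaxation but before the spike jumps.
#'
#' @param state an [stp_state()] object
#' @param params an [stp_params()] object
#' @param spikes integer indices of presynaptic neurons spiking this step
#' @param dt time step \[s\]
#' @return the updated state, with the delivered per-spiker efficacies in
#'   attribute `"efficacy"` (parallel to `spikes`)
#' @export
stp_step <- function(state, params, spikes = integer(0), dt) {
  stopifnot(dt > 0)
  fd <- exp(-dt / params$tau_d)
  ff <- exp(-dt / params$tau_f)
  state$x <- 1 + (state$x - 1) * fd
  state$u <- params$U_stp + (state$u - params$U_stp) * ff
  eff <- state$u[spikes] * state$x[spikes]
  if (length(spikes)) {
    u_new <- state$u[spikes] + params$U_stp * (1 - state$u[spikes])
    state$u[spikes] <- u_new
    state$x[spikes] <- state$x[spikes] - u_new * state$x[spikes]
  }
  attr(state, "efficacy") <- eff
  state
}

#' Spike-timing traces for the excitatory learning rule
#'
#' `z_plus` lives on the presynaptic side; `z_minus`, `z_slow` and `z_ht`
#' plus the homeostatic integrator `C` live on the postsynaptic side. All
#' traces obey \eqn{\dot z = -z/\tau + S(t)}; the homeostatically
#' regulated LTD rate is `B = A * min(C, 1)`.
#'
#' @param n_pre,n_post population sizes
#' @export
triplet_traces <- function(n_pre, n_post) {
  structure(list(
    z_plus = numeric(n_pre),
    z_minus = numeric(n_post), z_slow = numeric(n_post),
    z_ht = numeric(n_post), C = numeric(n_post)
  ), class = "triplet_traces")
}

#' Decay (and optionally increment) spike-timing traces
#'
#' Applies one step of exponential decay to every trace with its own time
#' constant, using the exact per-step decay factor (traces are linear, so
#' this is exact and stabler than Euler; membrane and conductances remain
#' forward Euler). If spike sets are supplied, the corresponding traces are
#' then incremented by 1. Rule evaluations triggered by this step's spikes
#' must read the traces after the decay but before these increments
#' (the `t - eps` convention): call once with `dt` only, evaluate the
#' rules, then call [trace_increment()].
#'
#' @param traces a [triplet_traces()] object
#' @param dt time step \[s\]
#' @param pre_spikes,post_spikes integer spike index sets for this step
#' @param params an [exc_plasticity_params()] object carrying the trace
#'   time constants
#' @return the updated traces
#' @export
trace_step <- function(traces, dt, pre_spikes = integer(0),
                       post_spikes = integer(0),
                       params = exc_plasticity_params()) {
  stopifnot(dt > 0)
  traces$z_plus <- traces$z_plus * exp(-dt / params$tau_plus)
  traces$z_minus <- traces$z_minus * exp(-dt / params$tau_minus)
  traces$z_slow <- traces$z_slow * exp(-dt / params$tau_slow)
  traces$z_ht <- traces$z_ht * exp(-dt / params$tau_ht)
  trace_increment(traces, pre_spikes, post_spikes)
}

#' @rdname trace_step
#' @export
trace_increment <- function(traces, pre_spikes = integer(0),
                            post_spikes = integer(0)) {
  if (length(pre_spikes))
    traces$z_plus[pre_spikes] <- traces$z_plus[pre_spikes] + 1
  if (length(post_spikes)) {
    traces$z_minus[post_spikes] <- traces$z_minus[post_spikes] + 1
    traces$z_slow[post_spikes] <- traces$z_slow[post_spikes] + 1
    traces$z_ht[post_spikes] <- traces$z_ht[post_spikes] + 1
  }
  traces
}

#' Presynaptic-spike terms of the excitatory rule (LTD and
#' transmitter-induced)
#'
#' For every synapse from `pre_id`, applies
#' `w <- w + eta_exc * (-B_i * z_minus_i) + delta` with
#' `B_i = A * min(C_i, 1)`, then clips to the projection bounds.
#'
#' @param proj a [sparse_projection()] with long-term plasticity
#' @param traces a [triplet_traces()] object (postsynaptic side of `proj`)
#' @param params an [exc_plasticity_params()] object
#' @param pre_id the presynaptic neuron that spiked
#' @return the projection with updated weights
#' @export
exc_on_pre_spike <- function(proj, traces, params, pre_id) {
  idx <- proj$by_src[[pre_id]]
  if (!length(idx)) return(proj)
  post <- proj$tgt[idx]
  B <- params$A * pmin(traces$C[post], 1)
  dw <- params$eta_exc * (-B * traces$z_minus[post]) + params$delta
  proj$w[idx] <- clip_w(proj$w[idx] + dw, proj$w_min, proj$w_max)
  proj
}

#' Postsynaptic-spike terms of the excitatory rule (triplet LTP and
#' heterosynaptic)
#'
#' For every synapse onto `post_id`, applies
#' `w <- w + eta_exc * A * z_plus_j * z_slow_i - beta * (w - w_tilde) *
#' z_minus_i^3`, then clips. The postsynaptic traces `z_slow` and
#' `z_minus` must be the pre-increment (`t - eps`) values, i.e. this is
#' called after the decay phase but before [trace_increment()].
#'
#' @inheritParams exc_on_pre_spike
#' @param post_id the postsynaptic neuron that spiked
#' @export
exc_on_post_spike <- function(proj, traces, params, post_id) {
  idx <- proj$by_tgt[[post_id]]
  if (!length(idx)) return(proj)
  pre <- proj$src[idx]
  wt <- if (is.null(proj$w_tilde)) proj$w[idx] else proj$w_tilde[idx]
  dw <- params$eta_exc * params$A * traces$z_plus[pre] * traces$z_slow[post_id] -
    params$beta * (proj$w[idx] - wt) * traces$z_minus[post_id]^3
  proj$w[idx] <- clip_w(proj$w[idx] + dw, proj$w_min, proj$w_max)
  proj
}

#' Update the homeostatic LTD integrator
#'
#' One forward-Euler step of \eqn{\dot C_i = -C_i/\tau^{hom} +
#' (z^{ht}_i)^2}, using the current (post-decay) value of the slow rate
#' trace `z_ht`. Trace increments themselves are handled by
#' [trace_step()]; the `post_spikes` argument is accepted for interface
#' symmetry but the rule needs only `z_ht`. The LTD rate implied is
#' `B = A * min(C, 1)`.
#'
#' @inheritParams exc_on_pre_spike
#' @param post_spikes unused; spikes enter through `z_ht`
#' @param dt time step \[s\]
#' @return the updated traces
#' @export
update_homeostasis <- function(traces, params, post_spikes = integer(0),
                               dt) {
  traces$C <- traces$C + dt * (-traces$C / params$tau_hom + traces$z_ht^2)
  traces
}

#' Consolidate reference weights (bistable double-well dynamics)
#'
#' One Euler step, with the long step `dt_long`, of
#' \deqn{\tau^{cons} \dot{\tilde w} = w - \tilde w - P \tilde w
#'   (w^P/2 - \tilde w)(w^P - \tilde w).}
#' For `w_P = 0.5` the cubic has a stable fixed point at
#' \eqn{\tilde w = 0} and an upper stable fixed point reached when
#' \eqn{w = \tilde w}; a weight held far above its reference collapses the
#' double well to a single high root. Reference weights are frozen between
#' consolidation ticks.
#'
#' @inheritParams exc_on_pre_spike
#' @param dt_long consolidation step \[s\] (much longer than the neural dt)
#' @return the projection with updated `w_tilde`
#' @export
consolidate_reference <- function(proj, params, dt_long) {
  if (is.null(proj$w_tilde)) return(proj)
  wt <- proj$w_tilde
  drift <- proj$w - wt -
    params$P * wt * (params$w_P / 2 - wt) * (params$w_P - wt)
  wt <- wt + dt_long / params$tau_cons * drift
  if (any(!is.finite(wt)) || any(abs(wt) > 1e6 * max(1, proj$w_max)))
    stop("consolidate_reference: reference weights diverging; ",
         "tau_cons/dt_long = ", format(params$tau_cons / dt_long),
         " is too small for a stable Euler step")
  proj$w_tilde <- wt
  proj
}

#' Inhibitory plasticity state
#'
#' Region-wide secreted factor `H` plus pre- (inhibitory) and post-
#' (excitatory) synaptic traces sharing one time constant.
#'
#' @param n_pre inhibitory population size
#' @param n_post excitatory population size
#' @export
inh_plasticity_state <- function(n_pre, n_post) {
  structure(list(H = 0, z_pre = numeric(n_pre), z_post = numeric(n_post)),
            class = "inh_plasticity_state")
}

#' One step of network activity-based inhibitory plasticity
#'
#' `H` is a low-pass filter of all excitatory spikes in the region
#' (time constant `tau_H`); the drive is `G = H - gamma`. After the decay
#' phase, every presynaptic (inhibitory) spike on synapse j->i applies
#' `w <- w + eta_inh * G * (z_i + 1)` and every postsynaptic (excitatory)
#' spike applies `w <- w + eta_inh * G * z_j`, with `G` and all traces
#' read at their pre-increment values; weights are clipped to the bounds.
#' Finally traces and `H` are incremented by this step's spikes.
#'
#' @param proj a [sparse_projection()] from inhibitory onto excitatory
#'   neurons
#' @param state an [inh_plasticity_state()] object
#' @param params an [inh_plasticity_params()] object
#' @param pre_spikes inhibitory spike indices this step
#' @param post_spikes excitatory spike indices this step (targets of
#'   `proj`)
#' @param region_exc_spikes index set of all excitatory spikes in the
#'   region this step, feeding `H`
#' @param dt time step \[s\]
#' @return list with updated `proj` and `state`
#' @export
inh_plasticity_step <- function(proj, state, params, pre_spikes = integer(0),
                                post_spikes = integer(0),
                                region_exc_spikes = integer(0), dt) {
  stopifnot(dt > 0)
  state$H <- state$H * exp(-dt / params$tau_H)
  state$z_pre <- state$z_pre * exp(-dt / params$tau_istdp)
  state$z_post <- state$z_post * exp(-dt / params$tau_istdp)
  G <- state$H - params$gamma
  for (j in pre_spikes) {
    idx <- proj$by_src[[j]]
    if (length(idx)) {
      dw <- params$eta_inh * G * (state$z_post[proj$tgt[idx]] + 1)
      proj$w[idx] <- clip_w(proj$w[idx] + dw, proj$w_min, proj$w_max)
    }
  }
  for (i in post_spikes) {
    idx <- proj$by_tgt[[i]]
    if (length(idx)) {
      dw <- params$eta_inh * G * state$z_pre[proj$src[idx]]
      proj$w[idx] <- clip_w(proj$w[idx] + dw, proj$w_min, proj$w_max)
    }
  }
  if (length(pre_spikes))
    state$z_pre[pre_spikes] <- state$z_pre[pre_spikes] + 1
  if (length(post_spikes))
    state$z_post[post_spikes] <- state$z_post[post_spikes] + 1
  state$H <- state$H + length(region_exc_spikes)
  list(proj = proj, state = state)
}
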