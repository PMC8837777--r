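#' Pure-R reference simulation engine
#'
#' A deliberately straightforward per-neuron implementation of the network
#' dynamics, composed from the exported single-step operations
#' ([integrate_membrane()], [detect_spikes_and_reset()],
#' [decay_and_deliver_conductances()], [stp_step()], [trace_step()],
#' [exc_on_pre_spike()], [exc_on_post_spike()], [update_homeostasis()],
#' [inh_plasticity_step()], [consolidate_reference()]). It follows the same
#' per-step update order as the compiled kernel (conductance delivery with
#' a one-step delay, then membrane integration, spike detection, trace
#' decay, rule evaluation on pre-increment traces, transmission queuing,
#' increments, and periodic reference-weight consolidation), so that the
#' two engines can be compared trajectory-for-trajectory on small networks.
#' External populations are driven by fixed spike schedules, which keeps
#' the comparison free of random-number-stream coupling.
#'
#' @param spec a resolved low-level network description, as produced by
#'   [build_network()] (see element `lowlevel` of the returned object)
#' @return an environment holding the mutable reference state
#' @export
reference_engine <- function(spec) {
  env <- new.env(parent = emptyenv())
  env$dt <- spec$dt
  env$dt_long <- spec$dt_long
  env$long_every <- max(1L, round(spec$dt_long / spec$dt))
  env$step_count <- 0L
  gp <- spec$global_plasticity
  env$gp <- gp
  env$stp <- stp_params(gp$U_stp, gp$tau_d, gp$tau_f)

  env$pops <- lapply(spec$pops, function(p) {
    list(name = p$name, n = p$n, stp = stp_state(p$n, env$stp),
         z_plus = numeric(p$n), eff = numeric(p$n), spikes = integer(0))
  })
  names(env$pops) <- vapply(spec$pops, `[[`, "", "name")

  env$regions <- lapply(spec$regions, function(r) {
    np <- do.call(neuron_params, r$neuron)
    n <- r$ne + r$ni
    list(name = r$name, ne = r$ne, ni = r$ni, np = np, tau_H = r$tau_H,
         trace_params = exc_plasticity_params(
           tau_plus = gp$tau_plus, tau_minus = gp$tau_minus,
           tau_slow = gp$tau_slow, tau_ht = gp$tau_ht,
           tau_hom = gp$tau_hom, P = gp$P, w_P = gp$w_P),
         state = region_state(n, np),
         exc_in = numeric(n), inh_in = numeric(n),
         prev_spikes = integer(0),
         stp = stp_state(r$ne, env$stp), eff = numeric(r$ne),
         traces = triplet_traces(r$ne, r$ne),
         istdp = inh_plasticity_state(r$ni, r$ne),
         sp_e = integer(0), sp_i = integer(0), enabled = TRUE)
  })
  names(env$regions) <- vapply(spec$regions, `[[`, "", "name")

  env$projs <- lapply(spec$projections, function(p) {
    pr <- sparse_projection(
      n_src = p$n_src, n_tgt = p$n_tgt, src = p$src_id, tgt = p$tgt_id,
      w = p$w, w_tilde = if (p$type == 2L) (p$w_tilde %||% p$w) else NULL,
      plastic_longterm = p$type == 2L, plastic_stp = p$type %in% c(1L, 2L),
      w_min = p$w_min, w_max = p$w_max)
    pr$meta <- p
    pr$exc_params <- exc_plasticity_params(
      eta_exc = p$eta, A = p$A, beta = p$beta, delta = p$delta,
      tau_plus = gp$tau_plus, tau_minus = gp$tau_minus,
      tau_slow = gp$tau_slow, tau_ht = gp$tau_ht, tau_hom = gp$tau_hom,
      tau_cons = if (p$tau_cons > 0) p$tau_cons else 1,
      P = gp$P, w_P = gp$w_P,
      w_min_exc = p$w_min, w_max_exc = p$w_max)
    pr
  })
  names(env$projs) <- vapply(spec$projections, `[[`, "", "name")
  env
}

ref_src_arrays <- function(env, meta) {
  if (meta$src_kind == 0L) env$pops[[meta$src]]
  else env$regions[[meta$src]]
}

#' Advance the reference engine
#'
#' @param env a [reference_engine()] environment
#' @param nsteps number of time steps
#' @param drive named list (by source population) of fixed spike
#'   schedules: each element a list with `spike_step` (1-based step within
#'   this call) and `spike_id`
#' @param record character vector of populations (`"STIM"`, `"HPC.e"`,
#'   `"HPC.i"`, ...) whose membrane/threshold trajectories and spikes to
#'   record
#' @return list with per-step `U` and `theta` matrices and spike rasters
#'   for the recorded populations
#' @export
reference_run <- function(env, nsteps, drive = list(), record = character(0)) {
  gp <- env$gp
  traj <- lapply(record, function(nm) list(U = NULL, theta = NULL,
                                           time = numeric(0), neuron = integer(0)))
  names(traj) <- record
  rec_parts <- lapply(record, function(nm) {
    if (nm %in% names(env$pops)) return(list(kind = "pop", name = nm))
    base <- sub("\\.[ei]$", "", nm)
    part <- sub("^.*\\.", "", nm)
    list(kind = part, name = base)
  })
  names(rec_parts) <- record

  for (s in seq_len(nsteps)) {
    ## phase A-C per region
    for (rn in names(env$regions)) {
      r <- env$regions[[rn]]
      if (!r$enabled) {
        r$sp_e <- integer(0); r$sp_i <- integer(0)
        env$regions[[rn]] <- r
        next
      }
      r$state <- decay_and_deliver_conductances(
        r$state, r$np, exc_input = r$exc_in, inh_input = r$inh_in,
        own_spikes = r$prev_spikes, dt = env$dt)
      r$exc_in[] <- 0; r$inh_in[] <- 0
      r$state <- integrate_membrane(r$state, r$np, env$dt)
      det <- detect_spikes_and_reset(r$state, r$np)
      r$state <- det$state
      r$prev_spikes <- det$spikes
      r$sp_e <- det$spikes[det$spikes <= r$ne]
      r$sp_i <- det$spikes[det$spikes > r$ne] - r$ne
      env$regions[[rn]] <- r
    }
    ## Poisson population spikes (fixed schedules only)
    for (pn in names(env$pops)) {
      p <- env$pops[[pn]]
      p$spikes <- integer(0)
      d <- drive[[pn]]
      if (!is.null(d)) p$spikes <- d$spike_id[d$spike_step == s]
      env$pops[[pn]] <- p
    }

    ## D1: trace/STP/homeostasis decays; D2 efficacies, jumps deferred by
    ## stp_step's atomic semantics (nothing reads u, x in between)
    for (rn in names(env$regions)) {
      r <- env$regions[[rn]]
      if (!r$enabled) next
      r$traces <- trace_step(r$traces, env$dt, params = r$trace_params)
      r$traces <- update_homeostasis(r$traces, r$trace_params, dt = env$dt)
      r$stp <- stp_step(r$stp, env$stp, spikes = r$sp_e, dt = env$dt)
      r$eff[r$sp_e] <- attr(r$stp, "efficacy")
      env$regions[[rn]] <- r
    }
    for (pn in names(env$pops)) {
      p <- env$pops[[pn]]
      p$z_plus <- p$z_plus * exp(-env$dt / gp$tau_plus)
      p$stp <- stp_step(p$stp, env$stp, spikes = p$spikes, dt = env$dt)
      p$eff[p$spikes] <- attr(p$stp, "efficacy")
      env$pops[[pn]] <- p
    }

    ## D3: plasticity rules (pre-rules then post-rules, per projection)
    for (qn in names(env$projs)) {
      pr <- env$projs[[qn]]
      meta <- pr$meta
      tr <- env$regions[[meta$tgt]]
      if (!tr$enabled) next
      if (meta$src_kind != 0L && !env$regions[[meta$src]]$enabled) next
      if (pr$plastic_longterm) {
        src <- ref_src_arrays(env, meta)
        pre_sp <- if (meta$src_kind == 0L) src$spikes else src$sp_e
        for (j in pre_sp) {
          if (pr$blocked[j]) next
          pr <- exc_on_pre_spike(pr, tr$traces, pr$exc_params, j)
        }
        zp_src <- if (meta$src_kind == 0L) src$z_plus else src$traces$z_plus
        tmp_traces <- tr$traces
        tmp_traces$z_plus <- zp_src
        for (i in tr$sp_e)
          pr <- exc_on_post_spike(pr, tmp_traces, pr$exc_params, i)
        env$projs[[qn]] <- pr
      } else if (meta$type == 3L) {
        ip <- inh_plasticity_params(
          eta_inh = meta$eta_inh, gamma = meta$gamma, tau_H = tr$tau_H,
          tau_istdp = gp$tau_istdp, w_min_inh = meta$w_min,
          w_max_inh = meta$w_max)
        pre_ok <- env$regions[[meta$src]]$sp_i
        pre_ok <- pre_ok[!pr$blocked[pre_ok]]
        res <- inh_plasticity_step(
          pr, tr$istdp, ip, pre_spikes = pre_ok, post_spikes = tr$sp_e,
          region_exc_spikes = tr$sp_e, dt = env$dt)
        res$proj$exc_params <- pr$exc_params
        res$proj$meta <- meta
        env$projs[[qn]] <- res$proj
        tr$istdp <- res$state
        env$regions[[meta$tgt]] <- tr
      }
    }
    ## iSTDP state decay for regions without a plastic I->E projection is
    ## irrelevant to the dynamics and skipped, matching nothing that is read.

    ## D4: transmission to next step's buffers (post-update weights)
    for (qn in names(env$projs)) {
      pr <- env$projs[[qn]]
      meta <- pr$meta
      tr <- env$regions[[meta$tgt]]
      if (!tr$enabled) next
      if (meta$src_kind != 0L && !env$regions[[meta$src]]$enabled) next
      src <- ref_src_arrays(env, meta)
      pre_sp <- if (meta$src_kind == 0L) src$spikes
      else if (meta$src_kind == 1L) src$sp_e else src$sp_i
      if (!length(pre_sp)) next
      use_stp <- meta$type %in% c(1L, 2L)
      off <- if (meta$tgt_part == 2L) tr$ne else 0L
      for (j in pre_sp) {
        if (pr$blocked[j]) next
        idx <- pr$by_src[[j]]
        if (!length(idx)) next
        e <- if (use_stp) src$eff[j] else 1
        contrib <- pr$w[idx] * e
        tgt_idx <- off + pr$tgt[idx]
        if (meta$src_kind == 2L) {
          tr$inh_in[tgt_idx] <- tr$inh_in[tgt_idx] + contrib
        } else {
          tr$exc_in[tgt_idx] <- tr$exc_in[tgt_idx] + contrib
        }
      }
      env$regions[[meta$tgt]] <- tr
    }

    ## D5: trace increments (STP jumps and H increments already applied by
    ## stp_step / inh_plasticity_step above)
    for (rn in names(env$regions)) {
      r <- env$regions[[rn]]
      if (!r$enabled) next
      r$traces <- trace_increment(r$traces, pre_spikes = r$sp_e,
                                  post_spikes = r$sp_e)
      env$regions[[rn]] <- r
    }
    for (pn in names(env$pops)) {
      p <- env$pops[[pn]]
      if (length(p$spikes))
        p$z_plus[p$spikes] <- p$z_plus[p$spikes] + 1
      env$pops[[pn]] <- p
    }

    env$step_count <- env$step_count + 1L
    if (env$step_count %% env$long_every == 0L) {
      for (qn in names(env$projs)) {
        pr <- env$projs[[qn]]
        if (pr$plastic_longterm) {
          pr <- consolidate_reference(pr, pr$exc_params, env$dt_long)
          env$projs[[qn]] <- pr
        }
      }
    }

    ## recording
    tsp <- env$step_count * env$dt
    for (nm in record) {
      rp <- rec_parts[[nm]]
      if (rp$kind == "pop") {
        sp <- env$pops[[rp$name]]$spikes
        traj[[nm]]$time <- c(traj[[nm]]$time, rep(tsp, length(sp)))
        traj[[nm]]$neuron <- c(traj[[nm]]$neuron, sp)
      } else {
        r <- env$regions[[rp$name]]
        rng <- if (rp$kind == "e") seq_len(r$ne) else r$ne + seq_len(r$ni)
        traj[[nm]]$U <- rbind(traj[[nm]]$U, r$state$U[rng])
        traj[[nm]]$theta <- rbind(traj[[nm]]$theta, r$state$theta[rng])
        sp <- if (rp$kind == "e") r$sp_e else r$sp_i
        traj[[nm]]$time <- c(traj[[nm]]$time, rep(tsp, length(sp)))
        traj[[nm]]$neuron <- c(traj[[nm]]$neuron, sp)
      }
    }
  }
  traj
}
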