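## Network and protocol presets.
##
## The desk scale (512 excitatory / 128 inhibitory neurons per region,
## 1024 stimulus cells, minutes of simulated time) keeps the 4:1 E/I ratio
## of the full-scale model and is the configuration exercised by the test
## and acceptance suites; the paper scale mirrors it at 4096/1024 per
## region with proportionally longer consolidation timescales. Region
## orderings are fixed by construction: subcortical (HPC, THL) learning
## rates exceed the cortical ones, and the STIM->HPC consolidation time
## constant exceeds every other excitatory tau_cons, which is what drives
## hippocampal de-maturation against cortical maturation.

preset_names <- c("two-region", "two-region-hpc-ctx-plastic",
                  "two-region-hpc-ctx-static",
                  "two-region-bidirectional",
                  "three-region", "three-region-rdt",
                  "two-cortical-reentrant")

#' Network presets for the standard configurations
#'
#' @param name preset name: `"two-region"` (unconnected HPC and CTX fed by
#'   STIM), its variants with plastic / static / bidirectional HPC-CTX
#'   projections, `"three-region"` (HPC -> THL -> CTX with circular
#'   receptive fields from STIM and external consolidation drive),
#'   `"three-region-rdt"` (plus a shared downstream readout region), and
#'   `"two-cortical-reentrant"` (three-region plus a second cortical
#'   region with reentrant cortical connectivity)
#' @param scale `"desk"` (512/128 per region) or `"paper"` (4096/1024)
#' @param seed master seed
#' @param ... overrides forwarded to [network_spec()]
#' @return a [network_spec()]
#' @export
network_preset <- function(name = preset_names,
                           scale = c("desk", "paper"), seed = 1, ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  ne <- if (desk) 512L else 4096L
  ni <- if (desk) 128L else 1024L
  n_stim <- if (desk) 1024L else 4096L
  rf <- if (desk) 3 else 5
  tau_cons_fast <- if (desk) 250 else 1200
  tau_cons_slow <- if (desk) 20000 else 86400
  eta_sub <- if (desk) 2e-3 else 2.5e-4
  eta_ctx <- eta_sub / 8
  delta_sub <- if (desk) 1.5e-4 else 2e-5
  delta_ctx <- delta_sub * 2 / 3
  eta_inh_sub <- if (desk) 5e-8 else 5e-7
  eta_inh_ctx <- eta_inh_sub / 4
  beta_reg <- 0.03
  beta_slow <- 0.1        # heterosynaptic anchor of the slow HPC afferents

  reg <- function(nm, eta, eta_inh, delta)
    region_spec(nm, N_exc = ne, N_inh = ni, eps_rec = 0.2,
                w_EE = 0.2, w_EI = 2, w_IE = 1, w_II = 1,
                eta_exc = eta, eta_inh = eta_inh, A = 1, beta = beta_reg,
                delta = delta, tau_cons = tau_cons_fast,
                target_rate = 3, tau_H = 10)
  hpc <- reg("HPC", eta_sub, eta_inh_sub, delta_sub)
  thl <- reg("THL", eta_sub, eta_inh_sub, delta_sub)
  ctx <- reg("CTX", eta_ctx, eta_inh_ctx, delta_ctx)

  p_stim_hpc <- projection_spec("STIM", "HPC", eps = 0.1, w0 = 0.4,
                                plasticity = "stp+longterm",
                                eta = eta_sub, delta = delta_sub,
                                beta = beta_slow,
                                tau_cons = tau_cons_slow)
  p_stim_ctx <- projection_spec("STIM", "CTX", eps = 0.1, w0 = 0.4,
                                plasticity = "stp+longterm",
                                eta = eta_ctx, delta = delta_ctx,
                                tau_cons = tau_cons_fast)
  two_region <- list(regions = list(hpc, ctx),
                     projections = list(p_stim_hpc, p_stim_ctx))
  hpc_ctx <- function(plast)
    projection_spec("HPC", "CTX", eps = 0.1, w0 = 0.2,
                    plasticity = plast, eta = eta_ctx, delta = delta_ctx,
                    tau_cons = tau_cons_fast)

  cfg <- switch(
    name,
    "two-region" = two_region,
    "two-region-hpc-ctx-plastic" = modifyList(two_region, list(
      projections = c(two_region$projections,
                      list(hpc_ctx("stp+longterm"))))),
    "two-region-hpc-ctx-static" = modifyList(two_region, list(
      projections = c(two_region$projections, list(hpc_ctx("stp"))))),
    "two-region-bidirectional" = modifyList(two_region, list(
      projections = c(two_region$projections, list(
        hpc_ctx("stp+longterm"),
        projection_spec("CTX", "HPC", eps = 0.1, w0 = 0.2,
                        plasticity = "stp+longterm", eta = eta_ctx,
                        delta = delta_ctx, tau_cons = tau_cons_fast))))),
    "three-region" = ,
    "three-region-rdt" = ,
    "two-cortical-reentrant" = {
      base <- list(
        regions = list(hpc, thl, ctx),
        projections = list(
          projection_spec("STIM", "HPC", kind = "circular", R = rf,
                          w0 = 0.4, plasticity = "stp+longterm",
                          eta = eta_sub, delta = delta_sub,
                          beta = beta_slow,
                          tau_cons = tau_cons_slow),
          projection_spec("STIM", "THL", kind = "circular", R = rf,
                          w0 = 1, plasticity = "stp"),
          projection_spec("HPC", "THL", eps = 0.2, w0 = 0.4,
                          plasticity = "stp+longterm", eta = eta_sub,
                          delta = delta_sub, tau_cons = tau_cons_fast),
          projection_spec("THL", "CTX", eps = 0.2, w0 = 1.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast)),
        ext = stats::setNames(c(n_stim, n_stim), c("HPC", "CTX")))
      if (name == "three-region-rdt") {
        base$regions <- c(base$regions,
                          list(reg("RDT", eta_ctx, eta_inh_ctx,
                                   delta_ctx)))
        base$projections <- c(base$projections, list(
          projection_spec("HPC", "RDT", eps = 0.1, w0 = 0.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast),
          projection_spec("CTX", "RDT", eps = 0.1, w0 = 0.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast)))
      } else if (name == "two-cortical-reentrant") {
        ctx2 <- reg("CTX2", eta_ctx, eta_inh_ctx, delta_ctx)
        base$regions <- c(base$regions, list(ctx2))
        base$projections <- c(base$projections, list(
          projection_spec("THL", "CTX2", eps = 0.1, w0 = 0.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast),
          projection_spec("CTX", "CTX2", eps = 0.1, w0 = 0.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast),
          projection_spec("CTX2", "CTX", eps = 0.1, w0 = 0.2,
                          plasticity = "stp+longterm", eta = eta_ctx,
                          delta = delta_ctx, tau_cons = tau_cons_fast)))
      }
      base
    })
  gp_desk <- list(tau_d = 0.05, tau_hom = 5, P = 10)
  args <- c(cfg, list(N_stim = n_stim, seed = seed,
                      global_plasticity = if (desk) gp_desk else list()))
  dots <- list(...)
  args[names(dots)] <- dots       # wholesale replacement of overridden keys
  do.call(network_spec, args)
}

#' Protocol presets matched to the network presets
#'
#' @inheritParams network_preset
#' @param ... overrides forwarded to [protocol_schedule()]
#' @return a [protocol_schedule()]
#' @export
protocol_preset <- function(name = preset_names,
                            scale = c("desk", "paper"), ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  base <- if (scale == "desk") {
    list(T_burn = 10, T_training = 400, T_consolidation = 600,
         T_testing = 40, T_on_training = 1, T_off_training = 2,
         T_on_testing = 1, T_off_testing = 3,
         nu_bg = 2, nu_stim = 75, nu_cons = 10, nu_ext_cons = 10,
         dt_eng = 100, test_times = c(0, 600))
  } else {
    list(T_burn = 60, T_training = 1800, T_consolidation = 43200,
         T_testing = 300, T_on_training = 1, T_off_training = 2,
         T_on_testing = 1, T_off_testing = 3,
         nu_bg = 2, nu_stim = 75, nu_cons = 10, nu_ext_cons = 10,
         dt_eng = 300, test_times = seq(0, 43200, by = 7200))
  }
  do.call(protocol_schedule, modifyList(base, list(...)))
}
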