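test_that("short-term plasticity relaxes to its fixed point and jumps per the rule", {
  p <- stp_params(U_stp = 0.2, tau_d = 0.2, tau_f = 0.6)
  st <- stp_state(1, p)
  st$u <- 0.9; st$x <- 0.1
  for (i in seq_len(20 * 600)) st <- stp_step(st, p, dt = 1e-3)
  expect_lt(abs(st$u - p$U_stp), 1e-6)
  expect_lt(abs(st$x - 1), 1e-6)

  # single spike from rest: u facilitates first, x depressed with the new u
  st <- stp_state(1, p)
  st <- stp_step(st, p, spikes = 1L, dt = 1e-9)
  u_after <- p$U_stp + p$U_stp * (1 - p$U_stp)
  expect_equal(st$u, u_after, tolerance = 1e-6)
  expect_equal(st$x, 1 - u_after, tolerance = 1e-6)
  # delivered efficacy is the pre-jump product
  expect_equal(attr(st, "efficacy"), p$U_stp * 1, tolerance = 1e-6)

  # state stays inside the unit square under random spiking
  st <- stp_state(5, p)
  set.seed(1)
  lo <- 1; hi <- 0
  for (i in 1:2000) {
    sp <- which(runif(5) < 0.05)
    st <- stp_step(st, p, spikes = sp, dt = 1e-3)
    lo <- min(lo, st$u, st$x); hi <- max(hi, st$u, st$x)
  }
  expect_gte(lo, 0)
  expect_lte(hi, 1)
})

test_that("mean transmitted efficacy under a Poisson train matches an event-driven oracle", {
  p <- stp_params()
  rate <- 20; dur <- 60; dt <- 1e-3
  set.seed(7)
  spikes <- which(runif(dur / dt) < rate * dt)
  # stepped path
  st <- stp_state(1, p)
  eff_step <- numeric(0)
  for (s in seq_len(dur / dt)) {
    sp <- if (s %in% spikes) 1L else integer(0)
    st <- stp_step(st, p, spikes = sp, dt = dt)
    if (length(sp)) eff_step <- c(eff_step, attr(st, "efficacy"))
  }
  # event-driven oracle: exact relaxation between spike times
  u <- p$U_stp; x <- 1; t_last <- 0
  eff_ev <- numeric(0)
  for (s in spikes) {
    tt <- s * dt
    x <- 1 + (x - 1) * exp(-(tt - t_last) / p$tau_d)
    u <- p$U_stp + (u - p$U_stp) * exp(-(tt - t_last) / p$tau_f)
    eff_ev <- c(eff_ev, u * x)
    u <- u + p$U_stp * (1 - u)
    x <- x - u * x
    t_last <- tt
  }
  expect_equal(mean(eff_step), mean(eff_ev), tolerance = 1e-10)
})

test_that("trace decay and increments follow the closed form with t-eps semantics", {
  pp <- exc_plasticity_params(tau_plus = 20e-3)
  tr <- triplet_traces(2, 2)
  tr$z_plus <- c(1, 0)
  n <- round(pp$tau_plus / 1e-4)
  for (i in seq_len(n)) tr <- trace_step(tr, 1e-4, params = pp)
  expect_equal(tr$z_plus[1], exp(-1), tolerance = 1e-12)

  # two spikes dt_gap apart: trace read at the second spike, before its
  # increment, equals exp(-gap/tau)
  gap <- 5e-3
  tr <- triplet_traces(1, 1)
  tr <- trace_step(tr, 1e-4, params = pp)      # decay phase of spike 1
  pre_increment_1 <- tr$z_plus
  tr <- trace_increment(tr, pre_spikes = 1L)
  for (i in seq_len(round(gap / 1e-4))) tr <- trace_step(tr, 1e-4, params = pp)
  expect_equal(pre_increment_1, 0)
  expect_equal(tr$z_plus, exp(-gap / pp$tau_plus), tolerance = 1e-12)
  tr <- trace_increment(tr, pre_spikes = 1L)
  expect_equal(tr$z_plus, 1 + exp(-gap / pp$tau_plus), tolerance = 1e-12)
})

make_proj <- function(n = 3, w = 0.5, w_tilde = NULL, w_max = 5) {
  grid <- expand.grid(src = 1:n, tgt = 1:n)
  sparse_projection(n, n, grid$src, grid$tgt, w = w, w_tilde = w_tilde,
                    plastic_longterm = TRUE, plastic_stp = TRUE,
                    w_min = 0, w_max = w_max)
}

test_that("presynaptic-spike rule applies LTD plus the transmitter-induced term", {
  pp <- exc_plasticity_params(eta_exc = 0.1, A = 2, delta = 0.01)
  tr <- triplet_traces(3, 3)

  # all z_minus zero, delta = 0: nothing changes
  p0 <- exc_plasticity_params(eta_exc = 0.1, A = 2, delta = 0)
  pr <- make_proj()
  pr2 <- exc_on_pre_spike(pr, tr, p0, 1L)
  expect_equal(pr2$w, pr$w)

  # scalar arithmetic: z_minus = c, C >= 1 so B = A
  tr$z_minus[] <- 0.3
  tr$C[] <- 2
  pr2 <- exc_on_pre_spike(pr, tr, pp, 2L)
  idx <- pr$by_src[[2]]
  expect_equal(pr2$w[idx],
               pr$w[idx] - 0.1 * 2 * 0.3 + 0.01, tolerance = 1e-14)
  expect_equal(pr2$w[-idx], pr$w[-idx])

  # silent targets, delta > 0: weights drift up by delta per spike, bounded
  tr0 <- triplet_traces(3, 3)
  pr <- make_proj(w = 4.995, w_max = 5)
  for (k in 1:3) pr <- exc_on_pre_spike(pr, tr0, pp, 1L)
  expect_true(all(pr$w[pr$by_src[[1]]] == 5))
})

test_that("postsynaptic-spike rule applies triplet LTP and the heterosynaptic pull", {
  pp <- exc_plasticity_params(eta_exc = 0.1, A = 2, beta = 0.5)
  tr <- triplet_traces(3, 3)

  pr <- make_proj(w = 1, w_tilde = 0.4)
  pr2 <- exc_on_post_spike(pr, tr, pp, 1L)
  expect_equal(pr2$w, pr$w)  # all traces zero

  tr$z_plus[] <- c(0.2, 0.5, 0.1)
  tr$z_slow[2] <- 1.5
  tr$z_minus[2] <- 0.8
  pr2 <- exc_on_post_spike(pr, tr, pp, 2L)
  idx <- pr$by_tgt[[2]]
  dw_expect <- 0.1 * 2 * tr$z_plus[pr$src[idx]] * 1.5 -
    0.5 * (1 - 0.4) * 0.8^3
  expect_equal(pr2$w[idx], pr$w[idx] + dw_expect, tolerance = 1e-14)
  expect_equal(pr2$w[-idx], pr$w[-idx])
})

test_that("repeated pre-before-post pairing potentiates under the triplet rule", {
  # event-driven scalar simulation: pre spike 10 ms before each post spike,
  # pairs at 5 Hz; LTD is weak at the low starting rate because C stays small
  pp <- exc_plasticity_params(eta_exc = 0.1, A = 1, beta = 0, delta = 0,
                              tau_hom = 10)
  pr <- sparse_projection(1, 1, 1L, 1L, w = 1, w_tilde = 1,
                          plastic_longterm = TRUE, w_min = 0, w_max = 10)
  tr <- triplet_traces(1, 1)
  dt <- 1e-4
  w0 <- pr$w
  for (pair in 1:20) {
    for (s in 1:2000) {          # 200 ms between pairs
      tr <- trace_step(tr, dt, params = pp)
      tr <- update_homeostasis(tr, pp, dt = dt)
      pre_sp <- s == 1000
      post_sp <- s == 1100      # +10 ms
      if (pre_sp) pr <- exc_on_pre_spike(pr, tr, pp, 1L)
      if (post_sp) pr <- exc_on_post_spike(pr, tr, pp, 1L)
      tr <- trace_increment(tr, pre_spikes = if (pre_sp) 1L else integer(0),
                            post_spikes = if (post_sp) 1L else integer(0))
    }
  }
  expect_gt(pr$w, w0)
})

test_that("homeostatic LTD rate saturates at A and matches the analytic steady state", {
  pp <- exc_plasticity_params(A = 2, tau_hom = 10, tau_ht = 100e-3)
  tr <- triplet_traces(1, 1)

  tr$C <- 2
  B <- pp$A * pmin(tr$C, 1)
  expect_equal(B, 2)           # saturation branch
  tr$C <- 0.5
  expect_equal(pp$A * pmin(tr$C, 1), 1)  # proportional branch

  # regular spiking at rate r for a long time: C -> tau_hom * (r * tau_ht)^2
  r <- 20; dt <- 1e-3
  tr <- triplet_traces(1, 1)
  for (i in seq_len(60 / dt)) {
    sp <- if (i %% round(1 / r / dt) == 0) 1L else integer(0)
    tr <- trace_step(tr, dt, post_spikes = sp, params = pp)
    tr <- update_homeostasis(tr, pp, dt = dt)
  }
  expect_equal(tr$C, pp$tau_hom * (r * pp$tau_ht)^2, tolerance = 0.05)
})

test_that("reference-weight consolidation has the documented fixed points", {
  pp <- exc_plasticity_params(P = 20, w_P = 0.5, tau_cons = 100)
  pr <- sparse_projection(1, 1, 1L, 1L, w = 0, w_tilde = 0,
                          plastic_longterm = TRUE, w_min = 0, w_max = 10)
  pr2 <- consolidate_reference(pr, pp, dt_long = 1.2)
  expect_equal(pr2$w_tilde, 0)          # lower fixed point

  pr$w <- 0.5; pr$w_tilde <- 0.5
  pr2 <- consolidate_reference(pr, pp, dt_long = 1.2)
  expect_equal(pr2$w_tilde, 0.5)        # upper fixed point at w = w_tilde

  # w >> w_tilde held fixed: w_tilde converges to the single real root of
  # the cubic, cross-checked against a root finder
  pr$w <- 3; pr$w_tilde <- 0
  for (i in 1:5000) pr <- consolidate_reference(pr, pp, dt_long = 1.2)
  root <- uniroot(function(wt) 3 - wt - pp$P * wt * (pp$w_P / 2 - wt) *
                    (pp$w_P - wt), c(0.4, 5), tol = 1e-12)$root
  expect_lt(abs(pr$w_tilde - root), 1e-4)

  # instability diagnostics name the timescale ratio
  pp_bad <- exc_plasticity_params(P = 2000, tau_cons = 0.1)
  pr$w <- 10; pr$w_tilde <- 5
  expect_error({
    for (i in 1:200) pr <- consolidate_reference(pr, pp_bad, dt_long = 1.2)
  }, "tau_cons")
})

test_that("inhibitory plasticity is gated by the activity difference G", {
  ip <- inh_plasticity_params(eta_inh = 0.1, gamma = 10, tau_H = 10)
  pr <- sparse_projection(2, 2, c(1, 1, 2), c(1, 2, 2), w = 1,
                          w_min = 0, w_max = 10)
  st <- inh_plasticity_state(2, 2)

  # H = gamma after decay: G = 0, no change on any spike
  st$H <- 10 / exp(-1e-4 / ip$tau_H)
  res <- inh_plasticity_step(pr, st, ip, pre_spikes = 1L, post_spikes = 2L,
                             region_exc_spikes = integer(0), dt = 1e-4)
  expect_equal(res$proj$w, pr$w, tolerance = 1e-9)

  # scalar arithmetic: pre spike with post trace c
  st <- inh_plasticity_state(2, 2)
  st$H <- 25; st$z_post <- c(0.4, 0.7)
  Hdec <- 25 * exp(-1e-4 / ip$tau_H)
  res <- inh_plasticity_step(pr, st, ip, pre_spikes = 1L,
                             region_exc_spikes = integer(0), dt = 1e-4)
  G <- Hdec - 10
  zdec <- c(0.4, 0.7) * exp(-1e-4 / ip$tau_istdp)
  expect_equal(res$proj$w[pr$by_src[[1]]],
               pr$w[pr$by_src[[1]]] + 0.1 * G * (zdec + 1),
               tolerance = 1e-12)
  # H integrates the region's excitatory spikes
  expect_equal(res$state$H, Hdec + 0)
  res2 <- inh_plasticity_step(pr, st, ip, region_exc_spikes = c(1L, 2L),
                              dt = 1e-4)
  expect_equal(res2$state$H, Hdec + 2)
})

test_that("excitatory rates above target strengthen total inhibition onto excitatory cells", {
  # closed fixture: excitatory cells driven at a rate whose low-pass H sits
  # above gamma; total I->E weight must increase over time
  ip <- inh_plasticity_params(eta_inh = 1e-3, gamma = 5, tau_H = 1)
  pr <- sparse_projection(2, 3, c(1, 1, 2, 2), c(1, 2, 2, 3), w = 1,
                          w_min = 0, w_max = 100)
  st <- inh_plasticity_state(2, 3)
  dt <- 1e-3
  set.seed(2)
  w_start <- sum(pr$w)
  for (i in seq_len(20 / dt)) {
    exc_sp <- which(runif(3) < 20 * dt)       # 20 Hz >> gamma/tau_H-equivalent
    inh_sp <- which(runif(2) < 10 * dt)
    res <- inh_plasticity_step(pr, st, ip, pre_spikes = inh_sp,
                               post_spikes = exc_sp,
                               region_exc_spikes = exc_sp, dt = dt)
    pr <- res$proj; st <- res$state
  }
  expect_gt(sum(pr$w), w_start)
})

test_that("weight bounds hold after every update and ablations zero exactly one term", {
  # bounds under a random storm of rule applications
  pp <- exc_plasticity_params(eta_exc = 5, A = 2, beta = 10, delta = 0.5,
                              w_min_exc = 0, w_max_exc = 2)
  pr <- make_proj(w = 1, w_tilde = 0.2, w_max = 2)
  tr <- triplet_traces(3, 3)
  set.seed(4)
  ok <- TRUE
  for (i in 1:300) {
    tr$z_plus <- runif(3, 0, 2); tr$z_minus <- runif(3, 0, 2)
    tr$z_slow <- runif(3, 0, 3); tr$C <- runif(3, 0, 2)
    pr <- exc_on_pre_spike(pr, tr, pp, sample(3, 1))
    pr <- exc_on_post_spike(pr, tr, pp, sample(3, 1))
    ok <- ok && all(pr$w >= 0 & pr$w <= 2)
  }
  expect_true(ok)

  # ablation semantics
  tr <- triplet_traces(3, 3)
  tr$z_plus[] <- 0.5; tr$z_minus[] <- 0.5; tr$z_slow[] <- 1; tr$C[] <- 1
  base <- make_proj(w = 1, w_tilde = 0.5)
  p_full <- exc_plasticity_params(eta_exc = 0.1, A = 1, beta = 0.4,
                                  delta = 0.02)
  p_noA <- exc_plasticity_params(eta_exc = 0.1, A = 0, beta = 0.4,
                                 delta = 0.02)
  p_nobeta <- exc_plasticity_params(eta_exc = 0.1, A = 1, beta = 0,
                                    delta = 0.02)
  p_nodelta <- exc_plasticity_params(eta_exc = 0.1, A = 1, beta = 0.4,
                                     delta = 0)
  pre_dw <- function(p) {
    out <- exc_on_pre_spike(base, tr, p, 1L)
    out$w[base$by_src[[1]]] - base$w[base$by_src[[1]]]
  }
  post_dw <- function(p) {
    out <- exc_on_post_spike(base, tr, p, 1L)
    out$w[base$by_tgt[[1]]] - base$w[base$by_tgt[[1]]]
  }
  # A = 0 removes both triplet terms and nothing else
  expect_equal(pre_dw(p_noA), pre_dw(p_full) + 0.1 * 1 * 0.5)
  expect_equal(post_dw(p_noA), post_dw(p_full) - 0.1 * 1 * 0.5 * 1)
  # beta = 0 removes only the heterosynaptic pull
  expect_equal(post_dw(p_nobeta), post_dw(p_full) + 0.4 * (1 - 0.5) * 0.5^3)
  expect_equal(pre_dw(p_nobeta), pre_dw(p_full))
  # delta = 0 removes only the transmitter-induced increment
  expect_equal(pre_dw(p_nodelta), pre_dw(p_full) - 0.02)
  expect_equal(post_dw(p_nodelta), post_dw(p_full))
})

test_that("inhibitory plasticity steers the excitatory rate toward its target", {
  # isolated fixture region under fixed Poisson drive: with a fast
  # inhibitory learning rate the mean excitatory rate approaches the
  # configured target
  spec <- network_spec(
    regions = list(
      region_spec("HPC", N_exc = 64, N_inh = 16, eps_rec = 0.6,
                  eta_exc = 0, eta_inh = 5e-6, A = 0, beta = 0, delta = 0,
                  tau_cons = 100, target_rate = 5,
                  w_EI = 2, w_IE = 0.5, w_max_inh = 100)),
    projections = list(
      projection_spec("STIM", "HPC", eps = 0.4, w0 = 0.5,
                      plasticity = "stp", eta = 0)),
    N_stim = 128, seed = 4, global_plasticity = list(tau_d = 0.05))
  net <- build_network(spec)
  drv <- list(STIM = list(active = integer(0), rate_active = 0,
                          rate_bg = 20))
  engramsim:::eng_seed(net$ptr, 11)
  engramsim:::eng_run(net$ptr, 150, drv, list())  # let the rule settle
  res <- engramsim:::eng_run(net$ptr, 30, drv, list(raster = "HPC.e"))
  rate <- length(res$rasters$HPC.e$time) / 64 / 30
  expect_lt(abs(rate - 5) / 5, 0.2)
})
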