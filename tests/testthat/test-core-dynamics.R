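test_that("membrane integration fixes the resting state and follows the Euler step", {
  np <- neuron_params(tau_m = 20e-3)
  st <- region_state(3, np)

  # resting fixed point: no conductances, U = U_rest stays put
  st1 <- integrate_membrane(st, np, dt = 1e-4)
  expect_equal(st1$U, rep(np$U_rest, 3))

  # hand-applied Euler step: U = U_rest + 10, g = 0, dt = 0.1 ms, tau = 20 ms
  st$U <- rep(np$U_rest + 10, 3)
  st2 <- integrate_membrane(st, np, dt = 1e-4)
  expect_equal(st2$U, rep(np$U_rest + 10 - 10 * (1e-4 / 20e-3), 3))

  # threshold decays towards its resting value
  st$theta <- rep(np$theta_spike, 3)
  st3 <- integrate_membrane(st, np, dt = 1e-4)
  expect_true(all(st3$theta < np$theta_spike))
})

test_that("clamped excitatory conductance drives U to the algebraic fixed point", {
  np <- neuron_params()
  st <- region_state(1, np)
  g <- 0.4
  # clamp g_ampa and g_nmda to g so g_exc = g at every step
  dt <- 1e-4
  for (i in seq_len(round(20 * np$tau_m / dt))) {
    st$g_ampa <- g; st$g_nmda <- g
    st <- integrate_membrane(st, np, dt)
  }
  fix <- (np$U_rest + g * np$U_exc) / (1 + g)
  expect_lt(abs(st$U - fix), 1e-6)
})

test_that("non-finite membrane state fails fast naming the neuron", {
  np <- neuron_params()
  st <- region_state(4, np)
  st$U[3] <- NaN
  expect_error(integrate_membrane(st, np, 1e-4), "neuron index 3")
})

test_that("spike detection resets exactly the spikers", {
  np <- neuron_params()
  st <- region_state(5, np)

  det <- detect_spikes_and_reset(st, np)
  expect_identical(det$spikes, integer(0))
  expect_equal(det$state$U, st$U)

  st$U[2] <- st$theta[2] + 1
  det <- detect_spikes_and_reset(st, np)
  expect_identical(det$spikes, 2L)
  expect_equal(det$state$U[2], np$U_rest)
  expect_equal(det$state$theta[2], np$theta_spike)
  expect_equal(det$state$U[-2], st$U[-2])
  expect_equal(det$state$theta[-2], st$theta[-2])
})

test_that("post-spike threshold decay matches the closed form", {
  np <- neuron_params(tau_thr = 5e-3)
  st <- region_state(1, np)
  st$theta <- np$theta_spike
  dt <- 1e-5
  n <- round(5 * np$tau_thr / dt)
  for (i in seq_len(n)) st <- integrate_membrane(st, np, dt)
  closed <- np$theta_rest +
    (np$theta_spike - np$theta_rest) * exp(-5)
  # Euler at fine dt tracks the exponential closely
  expect_lt(abs(st$theta - closed), 0.05)
  # and after ~7 tau the threshold is within 1% of rest
  for (i in seq_len(round(2 * np$tau_thr / dt))) st <- integrate_membrane(st, np, dt)
  expect_lt(abs(st$theta - np$theta_rest) / abs(np$theta_rest), 0.01)
})

test_that("conductance decay and delivery follow the stated order", {
  np <- neuron_params()
  st <- region_state(2, np)
  st$g_ampa <- c(1, 2); st$g_gaba <- c(0.5, 0); st$g_a <- c(0.1, 0.1)
  dt <- 1e-4
  st1 <- decay_and_deliver_conductances(st, np, exc_input = c(0.3, 0),
                                        inh_input = c(0, 0.2),
                                        own_spikes = 2L, dt = dt)
  expect_equal(st1$g_ampa, c(1, 2) * (1 - dt / np$tau_ampa) + c(0.3, 0))
  expect_equal(st1$g_gaba, c(0.5, 0) * (1 - dt / np$tau_gaba) + c(0, 0.2))
  expect_equal(st1$g_a, c(0.1, 0.1) * (1 - dt / np$tau_a) + c(0, np$Delta_a))
  # NMDA is a low-pass of the post-update AMPA value
  expect_equal(st1$g_nmda, dt / np$tau_nmda * st1$g_ampa)

  # homogeneous decay stays within Euler error of the exponential
  st <- region_state(1, np)
  st$g_ampa <- 1
  n <- round(np$tau_ampa / dt)
  for (i in seq_len(n)) st <- decay_and_deliver_conductances(st, np, dt = dt)
  expect_lt(abs(st$g_ampa - exp(-1)), dt / np$tau_ampa * 2)

  expect_error(decay_and_deliver_conductances(st, np, exc_input = -1, dt = dt),
               "nonnegative")
})

test_that("NMDA trace matches a dt/10 reference integration after an impulse", {
  np <- neuron_params()
  dt <- 1e-5
  st <- region_state(1, np)
  nsteps <- round(0.2 / dt)
  ga_traj <- numeric(nsteps)
  for (i in seq_len(nsteps)) {
    st <- decay_and_deliver_conductances(st, np,
                                         exc_input = if (i == 1) 1 else 0,
                                         dt = dt)
    ga_traj[i] <- st$g_ampa
  }
  # reference: integrate the NMDA low-pass at dt/10 against the same
  # (piecewise-constant) AMPA trajectory; ten fine Euler substeps with
  # constant input collapse to a closed geometric form
  f10 <- (1 - dt / 10 / np$tau_nmda)^10
  gn <- 0
  for (i in seq_len(nsteps)) gn <- ga_traj[i] + (gn - ga_traj[i]) * f10
  expect_lt(abs(st$g_nmda - gn) / gn, 1e-4)
})

test_that("with no input, U and theta relax monotonically to rest", {
  np <- neuron_params()
  st <- region_state(1, np)
  st$U <- -55; st$theta <- 0
  us <- numeric(200); ths <- numeric(200)
  for (i in 1:200) {
    st <- integrate_membrane(st, np, 1e-4)
    us[i] <- st$U; ths[i] <- st$theta
  }
  expect_true(all(diff(us) < 0))
  expect_true(all(diff(ths) < 0))
  expect_true(all(us > np$U_rest))
  expect_true(all(ths > np$theta_rest))
})

test_that("halving dt changes membrane trajectories at first order", {
  np <- neuron_params()
  run_traj <- function(dt, t_total = 20e-3) {
    st <- region_state(1, np)
    st$U <- -55
    g <- 0.3
    for (i in seq_len(round(t_total / dt))) {
      st$g_ampa <- g; st$g_nmda <- g
      st <- integrate_membrane(st, np, dt)
    }
    st$U
  }
  u1 <- run_traj(4e-4); u2 <- run_traj(2e-4); u4 <- run_traj(1e-4)
  # error ratio (u1-u2)/(u2-u4) ~ 2 for a first-order method
  expect_gt((u1 - u2) / (u2 - u4), 1.5)
  expect_lt((u1 - u2) / (u2 - u4), 2.5)
})
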