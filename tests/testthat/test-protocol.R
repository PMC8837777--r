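test_that("random non-overlapping stimuli partition the stated fraction", {
  st <- make_stimuli("random-nonoverlapping", 1024, 4, seed = 1)
  sizes <- vapply(st$stimuli, length, integer(1))
  expect_equal(sizes, rep(256L, 4))
  expect_equal(length(unique(unlist(st$stimuli))), 1024L)  # disjoint cover
  for (i in 1:4) {
    expect_equal(length(st$cues[[i]]), 128L)
    expect_true(all(st$cues[[i]] %in% st$stimuli[[i]]))
  }
  expect_error(make_stimuli("random-nonoverlapping", 100, 5, seed = 1),
               "disjoint")
})

test_that("overlapping stimuli overlap by the stimulus fraction on average", {
  st <- make_stimuli("random-overlapping", 1024, 12, seed = 2)
  ov <- c()
  for (i in 1:11) for (j in (i + 1):12)
    ov <- c(ov, length(intersect(st$stimuli[[i]], st$stimuli[[j]])))
  # expected overlap = 25% of a stimulus = 64 cells
  expect_lt(abs(mean(ov) - 64), 3 * sd(ov) / sqrt(length(ov)) + 2)
})

test_that("horizontal bars partition rows with central-column cues", {
  st <- make_stimuli("horizontal-bars", 1024, 4, seed = 1)  # 32 x 32 grid
  sizes <- vapply(st$stimuli, length, integer(1))
  expect_equal(sizes, rep(8L * 32L, 4))                     # 8 full rows
  expect_equal(sort(unlist(st$stimuli)), 1:1024)            # disjoint cover
  for (i in 1:4) {
    expect_equal(length(st$cues[[i]]), length(st$stimuli[[i]]) / 2L)
    expect_true(all(st$cues[[i]] %in% st$stimuli[[i]]))
    cols <- (st$cues[[i]] - 1) %% 32 + 1
    expect_setequal(unique(cols), 9:24)                     # central 50%
    rows <- (st$cues[[i]] - 1) %/% 32 + 1
    expect_equal(sort(unique(rows)), ((i - 1) * 8 + 1):(i * 8))
  }
})

test_that("schedules draw exponential on/off intervals with uniform identities", {
  expect_equal(nrow(schedule_events(0, 1, 1, 4, seed = 1)), 0L)

  ev <- schedule_events(6000, T_on = 1.5, T_off = 1, n_stimuli = 4, seed = 3)
  on_dur <- ev$t_off - ev$t_on
  # truncation at the phase end affects at most the final event
  on_dur <- head(on_dur, -1)
  expect_lt(abs(mean(on_dur) - 1.5), 3 * 1.5 / sqrt(length(on_dur)))
  expect_gt(nrow(ev), 1000)
  p <- chisq.test(tabulate(ev$stim, 4))$p.value
  expect_gt(p, 0.01)
  expect_true(all(ev$t_off <= 6000))
  expect_true(all(diff(ev$t_on) > 0))
})

test_that("poisson drive produces the stated counts and honours partial cues", {
  expect_equal(nrow(poisson_drive(1:10, 0, 0, 100, 1, 1e-3, seed = 1)), 0L)

  pd <- poisson_drive(1:50, 40, 5, 200, 10, 1e-3, seed = 2)
  n_act <- sum(pd$neuron <= 50)
  n_bg <- sum(pd$neuron > 50)
  expect_lt(abs(n_act - 50 * 40 * 10), 4 * sqrt(50 * 40 * 10))
  expect_lt(abs(n_bg - 150 * 5 * 10), 4 * sqrt(150 * 5 * 10))

  # only the cue subset is elevated
  rate_cue <- n_act / 50 / 10
  rate_rest <- n_bg / 150 / 10
  expect_gt(rate_cue, 5 * rate_rest)
  expect_error(poisson_drive(1:2, 2000, 0, 10, 1, 1e-3), "rate")
})

test_that("manipulations mask exactly what they claim", {
  fx <- make_fixture("micro", seed = 6)
  net <- build_network(fx$spec)
  labels <- list(exc = list(HPC = list(ensembles = list(c(1L, 2L)))),
                 inh = list(HPC = list(ensembles = list(1L))))
  # micro two-region has no inter-region projections, so engram-output
  # blocking must leave every mask empty
  apply_manipulation(net, manipulation("block-engram-output", region = "HPC"),
                     labels)
  for (pj in projection_names(net))
    expect_false(any(engramsim:::eng_get_block(net$ptr, pj)))

  # blocking inhibitory neurons masks both I->E and I->I efferents
  apply_manipulation(net,
                     manipulation("block-inhibitory-neurons", region = "HPC"))
  expect_true(all(engramsim:::eng_get_block(net$ptr, "HPC:IE")))
  expect_true(all(engramsim:::eng_get_block(net$ptr, "HPC:II")))
  expect_false(any(engramsim:::eng_get_block(net$ptr, "CTX:IE")))

  # plasticity-term knockouts zero exactly one parameter
  apply_manipulation(net, manipulation("ablate-plasticity-term",
                                       term = "heterosynaptic",
                                       region = NULL))
  expect_equal(engramsim:::eng_get_proj_param(net$ptr, "HPC:EE", "beta"), 0)
  expect_gt(engramsim:::eng_get_proj_param(net$ptr, "HPC:EE", "A"), 0)
  expect_gt(engramsim:::eng_get_proj_param(net$ptr, "HPC:EE", "delta"), 0)

  # scale-beta touches only the named projection
  b0 <- engramsim:::eng_get_proj_param(net$ptr, "CTX:EE", "beta")
  apply_manipulation(net, manipulation("scale-beta", projection = "CTX:EE",
                                       factor = 10))
  expect_equal(engramsim:::eng_get_proj_param(net$ptr, "CTX:EE", "beta"),
               10 * b0)
})

test_that("blocking a source silences its transmission but not local dynamics", {
  # three-population chain at micro scale: HPC -> CTX via an explicit
  # inter-region projection, so blocking is observable downstream
  spec <- network_spec(
    regions = list(
      region_spec("HPC", N_exc = 6, N_inh = 2, eps_rec = 0.6,
                  eta_exc = 1e-3, eta_inh = 1e-6, tau_cons = 50,
                  target_rate = 5),
      region_spec("CTX", N_exc = 6, N_inh = 2, eps_rec = 0.6,
                  eta_exc = 5e-4, eta_inh = 5e-7, tau_cons = 25,
                  target_rate = 5)),
    projections = list(
      projection_spec("STIM", "HPC", eps = 0.8, w0 = 1.5,
                      tau_cons = 100),
      projection_spec("HPC", "CTX", eps = 0.8, w0 = 2.5, tau_cons = 50)),
    N_stim = 12, seed = 2, dt = 1e-4, dt_long = 0.05,
    global_plasticity = list(tau_d = 0.05))
  net <- build_network(spec)
  drv <- list(STIM = list(active = 1:12, rate_active = 100, rate_bg = 0))

  base <- fork_network(net)
  engramsim:::eng_seed(base$ptr, 9)
  r0 <- engramsim:::eng_run(base$ptr, 1, drv,
                            list(raster = c("HPC.e", "CTX.e")))
  expect_gt(length(r0$rasters$HPC.e$time), 0)
  expect_gt(length(r0$rasters$CTX.e$time), 0)

  blocked <- fork_network(net)
  engramsim:::eng_set_block(blocked$ptr, "HPC->CTX", rep(TRUE, 6))
  engramsim:::eng_seed(blocked$ptr, 9)
  r1 <- engramsim:::eng_run(blocked$ptr, 1, drv,
                            list(raster = c("HPC.e", "CTX.e")))
  # HPC unchanged (same drive, same seed, local dynamics untouched)
  expect_identical(r1$rasters$HPC.e, r0$rasters$HPC.e)
  # CTX receives nothing
  expect_equal(length(r1$rasters$CTX.e$time), 0)

  # region ablation removes the region entirely
  abl <- fork_network(net)
  apply_manipulation(abl, manipulation("ablate-region", region = "HPC",
                                       phase = "testing"))
  engramsim:::eng_seed(abl$ptr, 9)
  r2 <- engramsim:::eng_run(abl$ptr, 1, drv,
                            list(raster = c("HPC.e", "CTX.e")))
  expect_equal(length(r2$rasters$HPC.e$time), 0)
  expect_equal(length(r2$rasters$CTX.e$time), 0)
})

test_that("run_protocol on the micro fixture is deterministic and well-formed", {
  fx <- make_fixture("micro", seed = 8)
  sched <- fx$schedule
  net1 <- build_network(fx$spec)
  run1 <- run_protocol(net1, fx$stimuli, sched, seed = 5,
                       record_inh = FALSE)
  net2 <- build_network(fx$spec)
  run2 <- run_protocol(net2, fx$stimuli, sched, seed = 5,
                       record_inh = FALSE)
  expect_identical(run1$train_events, run2$train_events)
  expect_identical(run1$labels$exc$HPC$rates, run2$labels$exc$HPC$rates)
  expect_identical(run1$tests[["0"]]$rasters, run2$tests[["0"]]$rasters)
  expect_identical(run1$snapshots, run2$snapshots)
  expect_s3_class(run1, "engram_run")
  expect_named(run1$tests, "0")
})
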