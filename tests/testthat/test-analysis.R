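test_that("population activity is a plain binned rate with conservation", {
  empty <- population_activity(data.frame(time = numeric(0),
                                          neuron = integer(0)),
                               subset = 1:10, bin = 10e-3, t_end = 0.1)
  expect_true(all(empty$rate == 0))

  # 10 neurons each spiking once inside one 10 ms bin -> 100 Hz
  r <- data.frame(time = seq(0.012, 0.0195, length.out = 10), neuron = 1:10)
  pa <- population_activity(r, subset = 1:10, bin = 10e-3, t_end = 0.03)
  expect_equal(pa$rate, c(0, 100, 0))

  # integral of the series equals total count / subset size
  set.seed(1)
  r2 <- data.frame(time = sort(runif(500, 0, 2)),
                   neuron = sample(1:20, 500, TRUE))
  pa2 <- population_activity(r2, subset = 1:20, bin = 10e-3, t_end = 2)
  expect_equal(sum(pa2$rate) * pa2$bin, 500 / 20)

  expect_error(population_activity(r, subset = integer(0)), "empty subset")
})

test_that("engram labeling thresholds stimulus-evoked rates", {
  events <- data.frame(stim = c(1L, 2L, 1L),
                       t_on = c(10, 14, 18), t_off = c(12, 16, 20))
  # neuron 1: 12 Hz during stimulus-1 windows, 2 Hz otherwise
  # neuron 2: 8 Hz during stimulus-1 windows (below the 10 Hz threshold)
  r <- rbind(regular_spikes(1, 12, 10, 12), regular_spikes(1, 12, 18, 20),
             regular_spikes(1, 2, 12, 18),
             regular_spikes(2, 8, 10, 12), regular_spikes(2, 8, 18, 20))
  r <- r[order(r$time), ]
  lb <- label_engrams(r, events, zeta_thr = 10, dt_eng = 10, t_end = 20,
                      n_neurons = 3)
  expect_equal(lb$ensembles[[1]], 1L)       # only the 12 Hz neuron
  expect_equal(lb$ensembles[[2]], integer(0))
  expect_equal(lb$rates[1, 1], 12, tolerance = 0.01)
  expect_equal(lb$rates[2, 1], 8, tolerance = 0.01)

  # silent raster -> no engram cells
  lb0 <- label_engrams(data.frame(time = numeric(0), neuron = integer(0)),
                       events, zeta_thr = 10, dt_eng = 10, t_end = 20,
                       n_neurons = 3)
  expect_true(all(lengths(lb0$ensembles) == 0))

  # raising the threshold never adds cells (monotonicity)
  lb5 <- label_engrams(r, events, zeta_thr = 5, dt_eng = 10, t_end = 20,
                       n_neurons = 3)
  for (s in 1:2)
    expect_true(all(lb$ensembles[[s]] %in% lb5$ensembles[[s]]))

  # a stimulus with no presentations in the window errors
  expect_error(label_engrams(r, events, zeta_thr = 10, dt_eng = 1,
                             t_end = 20, n_neurons = 3),
               "no presentations")
})

test_that("recall metrics implement the activation definitions by hand enumeration", {
  # 4 ensembles of 2 cells; 8 cues (2 per stimulus). Construct activation:
  # every cue activates its own ensemble, except cue 7 activates nothing;
  # cue 3 additionally activates ensemble 2.
  labels <- list(ensembles = lapply(1:4, function(e) (2 * e - 1):(2 * e)))
  class(labels) <- "engram_labels"
  ev <- data.frame(stim = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
                   t_on = seq(0, by = 2, length.out = 8),
                   t_off = seq(1, by = 2, length.out = 8))
  mk <- function(ens, q) {  # ensemble ens fires 20 Hz during cue q
    rbind(regular_spikes(2 * ens - 1, 20, ev$t_on[q], ev$t_off[q]),
          regular_spikes(2 * ens, 20, ev$t_on[q], ev$t_off[q]))
  }
  r <- do.call(rbind, c(
    lapply((1:8)[-7], function(q) mk(ev$stim[q], q)),
    list(mk(2L, 3L))))
  r <- r[order(r$time), ]
  m <- recall_metrics(r, labels, ev, zeta_thr = 10)
  expect_equal(m$tpr, 7 / 8)
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$fpr, (1 / 3) / 8)

  # all correct -> 1/1/0 ; none -> 0/0/0
  r_all <- do.call(rbind, lapply(1:8, function(q) mk(ev$stim[q], q)))
  m1 <- recall_metrics(r_all[order(r_all$time), ], labels, ev, 10)
  expect_equal(c(m1$accuracy, m1$tpr, m1$fpr), c(1, 1, 0))
  silent <- data.frame(time = 0.5, neuron = 1L)
  m0 <- recall_metrics(silent, labels, ev, 10)
  expect_equal(c(m0$accuracy, m0$tpr, m0$fpr), c(0, 0, 0))
  # invariants: accuracy <= tpr, all within [0, 1]
  for (m_ in list(m, m1, m0)) {
    expect_lte(m_$accuracy, m_$tpr)
    expect_true(all(unlist(m_[c("accuracy", "tpr", "fpr")]) >= 0))
    expect_true(all(unlist(m_[c("accuracy", "tpr", "fpr")]) <= 1))
  }
  expect_error(recall_metrics(r, labels, ev[0, ], 10), "empty test schedule")
})

test_that("bootstrap intervals behave at the edges and cover the mean", {
  expect_equal(unclass(bootstrap_ci(rep(0.7, 6), seed = 1)), c(0.7, 0.7),
               ignore_attr = TRUE)
  ci <- bootstrap_ci(rep(c(0, 1), 50), level = 0.9, n_boot = 2000, seed = 2)
  expect_lt(ci[1], 0.5); expect_gt(ci[2], 0.5)

  # coverage on Gaussian samples is near the nominal level
  set.seed(3)
  hits <- 0
  for (i in 1:200) {
    x <- rnorm(20, mean = 1)
    ci <- bootstrap_ci(x, level = 0.9, n_boot = 400, seed = i)
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.80)
  expect_lt(hits / 200, 0.97)
})

test_that("lag_max finds constructed shifts with the documented sign and ties", {
  set.seed(4)
  bin <- 10e-3
  a <- stats::filter(rnorm(4000), rep(1, 5), sides = 1)
  a[is.na(a)] <- 0
  # identical series: zero lag
  expect_equal(lag_max(a, a, bin = bin, max_lag = 5)$lag_max, 0)

  # b delayed by 2.5 s: the first series leads -> positive lag
  shift <- 250
  b <- c(rep(0, shift), a[1:(length(a) - shift)])
  lr <- lag_max(a, b, bin = bin, max_lag = 5)
  expect_equal(lr$lag_max, 2.5)
  # antisymmetry
  lr2 <- lag_max(b, a, bin = bin, max_lag = 5)
  expect_equal(lr2$lag_max, -2.5)

  # periodic series: the smallest-|lag| representative is returned
  t <- seq(0, 40, by = bin)
  p1 <- sin(2 * pi * t / 4)
  p2 <- sin(2 * pi * (t - 1) / 4)     # shift 1 s, period 4 s
  lp <- lag_max(p1, p2, bin = bin, max_lag = 10)
  expect_equal(lp$lag_max, 1, tolerance = 0.02)

  expect_error(lag_max(rep(1, 100), a[1:100], bin = bin, max_lag = 0.1),
               "zero-variance")
})

test_that("ensemble weight matrices and feedforward totals match direct computation", {
  # hand-built 6-neuron projection: strong within, weak between
  w <- expand.grid(src = 1:6, tgt = 1:6)
  same <- (w$src <= 3) == (w$tgt <= 3)
  w$w <- ifelse(same, 0.9, 0.1)
  labels <- structure(list(ensembles = list(1:3, 4:6)),
                      class = "engram_labels")
  M <- ensemble_weight_matrix(w, labels)
  expect_equal(M, matrix(c(0.9, 0.1, 0.1, 0.9), 2))

  ks <- ensemble_weight_ks(w, labels)
  expect_equal(ks$statistic, 1)       # fully separated distributions
  expect_lt(ks$p_value, 1e-6)

  # uniform weights -> constant matrix
  w$w <- 0.5
  expect_true(all(ensemble_weight_matrix(w, labels) == 0.5))

  # cumulative feedforward totals: degenerate and direct cases
  ff <- data.frame(src = rep(1:4, each = 2), tgt = rep(c(2, 5), 4),
                   w = 0.25)
  cf <- cumulative_ff_weight(ff, labels)
  expect_equal(unname(cf$totals[c("2", "5")]), c(1, 1))
  expect_equal(cf$ecdf(1), 1)
  set.seed(5)
  ff$w <- runif(8)
  cf2 <- cumulative_ff_weight(ff, labels)
  expect_equal(unname(cf2$totals["2"]), sum(ff$w[ff$tgt == 2]))
})

test_that("statistical tests match brute-force references and route correctly", {
  x <- c(1.2, 3.4, 0.5, 2.2); y <- c(2.0, 4.1, 3.9)
  ks <- stat_tests(x, x, "ks")
  expect_equal(ks$statistic, 0)

  # Mann-Whitney U equals the exhaustive pair count
  mw <- stat_tests(x, y, "mannwhitney")
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mw$statistic, U)

  # Welch on two shifted Gaussians has power at large n
  set.seed(6)
  a <- rnorm(200); b <- rnorm(200, mean = 0.6, sd = 2)
  w <- stat_tests(a, b, "welch")
  expect_lt(w$p_value, 0.05)
  expect_true(w$reject)

  # auto-routing: normal equal-variance -> t; non-normal -> Mann-Whitney
  set.seed(7)
  expect_equal(stat_tests(rnorm(50), rnorm(50), "auto")$kind, "ttest")
  expect_equal(stat_tests(rexp(50), rexp(50), "auto")$kind, "mannwhitney")
})

test_that("the fast cross-correlation path agrees with the exact one", {
  set.seed(9)
  n <- 4000
  a <- as.numeric(stats::filter(rnorm(n), rep(1, 8), sides = 1)); a[is.na(a)] <- 0
  b <- c(rep(0, 120), a[1:(n - 120)])
  exact <- lag_max(a, b, bin = 0.01, max_lag = 3)       # n*L below cutover
  # force the FFT path by replicating the series beyond the cutover
  a2 <- rep(a, 10); b2 <- rep(b, 10)
  fast <- lag_max(a2, b2, bin = 0.01, max_lag = 30)
  expect_equal(exact$lag_max, 1.2)
  expect_equal(fast$lag_max, exact$lag_max)
})
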