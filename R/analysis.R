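#' @importFrom stats cor ks.test wilcox.test t.test shapiro.test median
#'   quantile anova lm sd
NULL

as_raster <- function(raster) {
  if (is.data.frame(raster)) list(time = raster$time, neuron = raster$neuron)
  else raster
}

#' Binned population activity
#'
#' Average firing rate of a neuron subset in fixed bins, computed as the
#' spike count of the subset per bin divided by `|subset| * bin` — no
#' smoothing or convolution.
#'
#' @param raster spike raster: data frame or list with `time` \[s\] and
#'   `neuron`
#' @param subset integer indices of the neurons to average over
#' @param bin bin width \[s\] (default 10 ms)
#' @param t_start,t_end window covered by the series (defaults to
#'   `[0, max(time)]` rounded up to a full bin)
#' @return list with `time` (bin start times), `rate` \[Hz\], `bin`
#' @export
population_activity <- function(raster, subset, bin = 10e-3,
                                t_start = 0, t_end = NULL) {
  stopifnot(bin > 0)
  if (!length(subset)) stop("population_activity: empty subset")
  r <- as_raster(raster)
  if (is.null(t_end))
    t_end <- if (length(r$time)) max(r$time) else t_start + bin
  nbins <- max(1L, ceiling((t_end - t_start) / bin - 1e-9))
  keep <- r$neuron %in% subset & r$time > t_start &
    r$time <= t_start + nbins * bin
  idx <- pmin(pmax(ceiling((r$time[keep] - t_start) / bin - 1e-9), 1), nbins)
  counts <- tabulate(idx, nbins)
  list(time = t_start + (seq_len(nbins) - 1) * bin,
       rate = counts / (length(subset) * bin), bin = bin)
}

#' Label engram cells from stimulus-evoked firing rates
#'
#' A neuron is an engram cell for a stimulus if its average firing rate
#' over that stimulus's presentation windows, within the final `dt_eng` of
#' the training phase, exceeds `zeta_thr`. A neuron may belong to several
#' ensembles.
#'
#' @param raster spike raster of one population covering the end of
#'   training
#' @param events training presentation table with columns `stim`, `t_on`,
#'   `t_off` (absolute times)
#' @param zeta_thr rate threshold \[Hz\] (default 10)
#' @param dt_eng labeling window: only presentations inside the final
#'   `dt_eng` seconds (up to `t_end`) count \[s\]
#' @param t_end end of the training phase \[s\]
#' @param n_neurons population size
#' @return an object of class `engram_labels`: per-stimulus index sets in
#'   `ensembles` plus the evoked-rate matrix
#' @export
label_engrams <- function(raster, events, zeta_thr = 10, dt_eng = 300,
                          t_end = max(events$t_off), n_neurons) {
  r <- as_raster(raster)
  w0 <- t_end - dt_eng
  k <- max(events$stim)
  rates <- matrix(0, n_neurons, k)
  for (s in seq_len(k)) {
    ev <- events[events$stim == s & events$t_off > w0, , drop = FALSE]
    if (!nrow(ev))
      stop("label_engrams: no presentations of stimulus ", s,
           " within the labeling window")
    ev$t_on <- pmax(ev$t_on, w0)
    ev <- ev[order(ev$t_on), , drop = FALSE]
    total <- sum(ev$t_off - ev$t_on)
    # windows are disjoint and sorted: a spike is inside one iff its
    # position in the interleaved boundary vector is odd
    bounds <- as.vector(rbind(ev$t_on, ev$t_off))
    inside <- findInterval(r$time, bounds) %% 2L == 1L
    cnt <- tabulate(r$neuron[inside], n_neurons)
    rates[, s] <- cnt / total
  }
  ensembles <- lapply(seq_len(k), function(s) which(rates[, s] > zeta_thr))
  structure(list(ensembles = ensembles, rates = rates,
                 zeta_thr = zeta_thr, dt_eng = dt_eng,
                 n_neurons = as.integer(n_neurons)),
            class = "engram_labels")
}

#' @export
print.engram_labels <- function(x, ...) {
  cat("<engram_labels>", length(x$ensembles), "ensembles; sizes:",
      paste(vapply(x$ensembles, length, integer(1)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Recall metrics from cue-evoked ensemble activation
#'
#' An ensemble counts as activated by a cue presentation if its mean
#' population rate over the full cue-on window exceeds `zeta_thr`. The
#' true positive rate is the fraction of cue presentations activating the
#' ensemble encoding the cued stimulus; the false positive rate is the
#' fraction of the other `k - 1` ensembles activated, averaged over
#' presentations; accuracy is the fraction of presentations in which only
#' the correct ensemble was activated. An empty ensemble never counts as
#' activated.
#'
#' @param raster spike raster of the readout population during testing
#' @param labels an [label_engrams()] result for the same population
#' @param test_events cue presentation table (`stim`, `t_on`, `t_off`,
#'   absolute times)
#' @param zeta_thr activation threshold \[Hz\]
#' @return list with `accuracy`, `tpr`, `fpr`, `n_cues` and the per-cue
#'   activation matrix
#' @export
recall_metrics <- function(raster, labels, test_events, zeta_thr = 10) {
  if (!nrow(test_events)) stop("recall_metrics: empty test schedule")
  k <- length(labels$ensembles)
  if (!any(vapply(labels$ensembles, length, integer(1)) > 0))
    stop("recall_metrics: all ensembles empty")
  r <- as_raster(raster)
  n_cues <- nrow(test_events)
  act <- matrix(FALSE, n_cues, k)
  for (q in seq_len(n_cues)) {
    dur <- test_events$t_off[q] - test_events$t_on[q]
    keep <- r$time > test_events$t_on[q] & r$time <= test_events$t_off[q]
    nrn <- r$neuron[keep]
    for (e in seq_len(k)) {
      ens <- labels$ensembles[[e]]
      if (!length(ens)) next
      rate <- sum(nrn %in% ens) / (length(ens) * dur)
      act[q, e] <- rate > zeta_thr
    }
  }
  own <- act[cbind(seq_len(n_cues), test_events$stim)]
  others <- vapply(seq_len(n_cues), function(q)
    sum(act[q, -test_events$stim[q]]), numeric(1))
  list(accuracy = mean(own & others == 0),
       tpr = mean(own),
       fpr = mean(others / (k - 1)),
       n_cues = n_cues, activation = act)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values per-trial metric values
#' @param level confidence level (default 0.90)
#' @param n_boot number of resamples
#' @param seed seed for the resampling
#' @return numeric vector `c(lower, upper)` with attribute `"mean"`
#' @export
bootstrap_ci <- function(values, level = 0.90, n_boot = 10000, seed = 1) {
  stopifnot(length(values) >= 1)
  means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      mean(sample(values, length(values), replace = TRUE)), numeric(1))
  })
  a <- (1 - level) / 2
  ci <- unname(quantile(means, c(a, 1 - a), type = 7))
  attr(ci, "mean") <- mean(values)
  ci
}

#' Lag maximizing the cross-correlation of two activity series
#'
#' Computes the Pearson correlation of the mean-subtracted series at every
#' lag in `[-max_lag, max_lag]` and returns the lag with the maximal
#' correlation. Ties are broken towards the smallest `|lag|` (and towards
#' the nonnegative lag between `+l` and `-l`). A positive lag means the
#' first series leads the second (`b` is shifted later in time).
#'
#' @param activity_a,activity_b rate series (numeric vectors or
#'   [population_activity()] results) with a common bin width
#' @param bin bin width \[s\] (taken from the inputs when they carry one)
#' @param max_lag maximum absolute lag searched \[s\]
#' @return an object of class `lag_result`: `lag_max` \[s\], `cor_max`,
#'   `bin`, `max_lag`
#' @export
lag_max <- function(activity_a, activity_b, bin = NULL, max_lag) {
  a <- if (is.list(activity_a)) activity_a$rate else activity_a
  b <- if (is.list(activity_b)) activity_b$rate else activity_b
  if (is.null(bin)) {
    bin <- if (is.list(activity_a)) activity_a$bin else
      stop("lag_max: bin width required")
    if (is.list(activity_b) && !isTRUE(all.equal(bin, activity_b$bin)))
      stop("lag_max: series have different bin widths")
  }
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  if (sd(a) == 0 || sd(b) == 0)
    stop("lag_max: zero-variance series")
  L <- min(n - 2L, round(max_lag / bin))
  lags <- -L:L
  if (as.double(n) * L <= 2.5e7) {
    # exact per-lag Pearson on the overlapping windows
    cors <- vapply(lags, function(l) {
      if (l >= 0) cor(a[seq_len(n - l)], b[seq_len(n - l) + l])
      else cor(a[seq_len(n + l) - l], b[seq_len(n + l)])
    }, numeric(1))
  } else {
    # FFT cross-correlation for long recordings: globally mean-subtracted
    # and sd-normalized, covariance estimated over the per-lag overlap
    am <- a - mean(a); bm <- b - mean(b)
    cc <- stats::convolve(am, bm, conj = TRUE, type = "open")
    # cc[k] = sum_t am[t] * bm[t - (k - n)] so lag l (second series later)
    # sits at index n - l
    sel <- n - lags
    cors <- cc[sel] / ((n - abs(lags)) * sd(a) * sd(b))
  }
  cors[is.na(cors)] <- -Inf
  best <- max(cors)
  cand <- lags[cors >= best - 1e-12]
  pick <- cand[order(abs(cand), cand < 0)][1]
  structure(list(lag_max = pick * bin, cor_max = best, bin = bin,
                 max_lag = L * bin,
                 profile = data.frame(lag = lags * bin, cor = cors)),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat("<lag_result> lag_max =", format(x$lag_max), "s (cor =",
      format(x$cor_max, digits = 3), ")\n")
  invisible(x)
}

#' Ensemble-clustered mean weight matrix
#'
#' Entry (a, b) is the mean weight over synapses from source cells in
#' ensemble b onto target cells in ensemble a; the diagonal summarizes
#' within-ensemble synapses, the off-diagonal inter-ensemble synapses.
#'
#' @param weights sparse triplet table (`src`, `tgt`, `w`), e.g. from
#'   [snapshot_weights()]
#' @param labels_source,labels_target [label_engrams()] results for the
#'   two sides (defaults to `labels_source` for recurrent projections)
#' @return a k x k matrix (target ensembles in rows)
#' @export
ensemble_weight_matrix <- function(weights, labels_source,
                                   labels_target = labels_source) {
  k <- length(labels_source$ensembles)
  out <- matrix(NA_real_, k, k)
  for (a in seq_len(k)) {
    ta <- labels_target$ensembles[[a]]
    if (!length(ta)) stop("ensemble_weight_matrix: empty target ensemble ", a)
    for (b in seq_len(k)) {
      sb <- labels_source$ensembles[[b]]
      if (!length(sb)) stop("ensemble_weight_matrix: empty source ensemble ", b)
      sel <- weights$src %in% sb & weights$tgt %in% ta
      out[a, b] <- if (any(sel)) mean(weights$w[sel]) else NaN
    }
  }
  out
}

#' Within- versus inter-ensemble weight distributions
#'
#' Returns the synapse-level weight samples among engram cells encoding
#' the same stimulus (diagonal blocks) and among engram cells encoding
#' different stimuli (off-diagonal blocks), plus the two-sided
#' Kolmogorov-Smirnov comparison between the two distributions.
#'
#' @inheritParams ensemble_weight_matrix
#' @export
ensemble_weight_ks <- function(weights, labels_source,
                               labels_target = labels_source) {
  k <- length(labels_source$ensembles)
  within <- numeric(0); between <- numeric(0)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    sel <- weights$src %in% labels_source$ensembles[[b]] &
      weights$tgt %in% labels_target$ensembles[[a]]
    if (a == b) within <- c(within, weights$w[sel])
    else between <- c(between, weights$w[sel])
  }
  ks <- suppressWarnings(ks.test(within, between))
  list(within = within, between = between,
       statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Total afferent weight onto individual engram cells
#'
#' For each engram cell of the target population (union over ensembles or
#' one ensemble), the sum of its afferent weights in the projection; the
#' empirical cumulative distribution of these totals is the classical
#' summary of feedforward maturation.
#'
#' @inheritParams ensemble_weight_matrix
#' @param labels_target target-side engram labels
#' @param ensemble optional single ensemble index (default: union)
#' @return list with per-cell `totals` (named by cell) and the `ecdf`
#' @export
cumulative_ff_weight <- function(weights, labels_target, ensemble = NULL) {
  cells <- if (is.null(ensemble))
    sort(unique(unlist(labels_target$ensembles)))
  else labels_target$ensembles[[ensemble]]
  if (!length(cells)) stop("cumulative_ff_weight: no labeled cells")
  totals <- vapply(cells, function(i)
    sum(weights$w[weights$tgt == i]), numeric(1))
  names(totals) <- cells
  list(totals = totals, ecdf = stats::ecdf(totals))
}

levene_p <- function(a, b) {
  za <- abs(a - median(a)); zb <- abs(b - median(b))
  g <- factor(c(rep("a", length(a)), rep("b", length(b))))
  fit <- lm(c(za, zb) ~ g)
  anova(fit)$`Pr(>F)`[1]
}

#' Two-sample statistical tests with the standard routing
#'
#' Two-sided tests at the 0.05 rejection level. `kind = "auto"` routes the
#' comparison the conventional way for activation-rate data: an unpaired
#' t-test when both samples pass Shapiro-Wilk normality (at 0.05) and a
#' Levene test finds equal variances, Welch's t-test when normal with
#' unequal variances, and Mann-Whitney otherwise.
#'
#' @param sample_a,sample_b numeric samples
#' @param kind `"mannwhitney"`, `"ks"`, `"ttest"`, `"welch"` or `"auto"`
#' @return list with `statistic`, `p_value`, `kind`, `reject` (at 0.05)
#' @export
stat_tests <- function(sample_a, sample_b,
                       kind = c("mannwhitney", "ks", "ttest", "welch",
                                "auto")) {
  kind <- match.arg(kind)
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (kind == "auto") {
    normal <- tryCatch(
      shapiro.test(sample_a)$p.value > 0.05 &&
        shapiro.test(sample_b)$p.value > 0.05,
      error = function(e) FALSE)
    kind <- if (!normal) "mannwhitney"
    else if (levene_p(sample_a, sample_b) > 0.05) "ttest" else "welch"
  }
  res <- switch(kind,
    mannwhitney = {
      h <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    ks = {
      h <- suppressWarnings(ks.test(sample_a, sample_b))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    ttest = {
      h <- t.test(sample_a, sample_b, var.equal = TRUE)
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    welch = {
      h <- t.test(sample_a, sample_b, var.equal = FALSE)
      list(statistic = unname(h$statistic), p_value = h$p.value)
    })
  res$kind <- kind
  res$reject <- res$p_value < 0.05
  res
}

#' Consolidation-phase ensemble activity series from a run
#'
#' Converts the binned spike counts recorded during consolidation into
#' per-ensemble rate series (Hz).
#'
#' @param run an `engram_run` from [run_protocol()]
#' @param group ensemble name, e.g. `"CTX.e.1"` (region, part, stimulus)
#' @return a [population_activity()]-style list
#' @export
consolidation_activity <- function(run, group) {
  cz <- run$consolidation
  gi <- match(group, cz$groups)
  if (is.na(gi)) stop("unknown ensemble group: ", group)
  counts <- cz$counts[, gi]
  list(time = cz$t0 + (seq_along(counts) - 1) * cz$bin,
       rate = counts / (cz$group_sizes[[gi]] * cz$bin), bin = cz$bin)
}
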