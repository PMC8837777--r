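#' @importFrom stats rexp
NULL

#' Generate training stimuli and their partial cues
#'
#' Three stimulus families are supported. `"random-nonoverlapping"` draws
#' each stimulus as a random subset comprising `fraction` of the stimulus
#' population, with pairwise-disjoint supports. `"random-overlapping"`
#' draws each stimulus independently (expected pairwise overlap equals
#' `fraction` of a stimulus). `"horizontal-bars"` partitions the rows of
#' the square stimulus grid into `n_stimuli` full-width bars. Cues are a
#' random `cue_fraction` of the stimulus for the random kinds, and the
#' central `cue_fraction` of the bar's columns (at full bar height) for
#' bars.
#'
#' @param kind stimulus family
#' @param N_stim stimulus population size
#' @param n_stimuli number of stimuli
#' @param fraction active fraction per stimulus (default 25%)
#' @param cue_fraction cue fraction of the stimulus (default 50%)
#' @param seed seed for the index draws
#' @return an object of class `stimulus_set` with index sets `stimuli`
#'   and `cues`
#' @export
make_stimuli <- function(kind = c("random-nonoverlapping",
                                  "random-overlapping", "horizontal-bars"),
                         N_stim, n_stimuli = 4, fraction = 0.25,
                         cue_fraction = 0.5, seed = 1) {
  kind <- match.arg(kind)
  size <- round(fraction * N_stim)
  out <- with_seed(seed, {
    if (kind == "random-nonoverlapping") {
      if (n_stimuli * size > N_stim)
        stop("make_stimuli: cannot draw ", n_stimuli,
             " disjoint stimuli of ", size, " cells from ", N_stim)
      perm <- sample.int(N_stim)
      stimuli <- lapply(seq_len(n_stimuli), function(i)
        sort(perm[((i - 1) * size + 1):(i * size)]))
      cues <- lapply(stimuli, function(s)
        sort(sample(s, round(cue_fraction * length(s)))))
      list(stimuli = stimuli, cues = cues, grid = NULL)
    } else if (kind == "random-overlapping") {
      stimuli <- lapply(seq_len(n_stimuli), function(i)
        sort(sample.int(N_stim, size)))
      cues <- lapply(stimuli, function(s)
        sort(sample(s, round(cue_fraction * length(s)))))
      list(stimuli = stimuli, cues = cues, grid = NULL)
    } else {
      side <- round(sqrt(N_stim))
      if (side^2 != N_stim)
        stop("make_stimuli: horizontal bars require a square grid")
      if (side %% n_stimuli != 0)
        stop("make_stimuli: grid side must be divisible by n_stimuli")
      rows_per <- side %/% n_stimuli
      c0 <- floor(side * (1 - cue_fraction) / 2)
      cue_cols <- (c0 + 1):(c0 + round(side * cue_fraction))
      stimuli <- list(); cues <- list()
      for (i in seq_len(n_stimuli)) {
        rows <- ((i - 1) * rows_per + 1):(i * rows_per)
        cells <- as.vector(outer((rows - 1) * side, seq_len(side), `+`))
        cue <- as.vector(outer((rows - 1) * side, cue_cols, `+`))
        stimuli[[i]] <- sort(cells); cues[[i]] <- sort(cue)
      }
      list(stimuli = stimuli, cues = cues, grid = c(side, side))
    }
  })
  structure(list(kind = kind, N_stim = as.integer(N_stim),
                 n_stimuli = as.integer(n_stimuli),
                 fraction = fraction, cue_fraction = cue_fraction,
                 stimuli = out$stimuli, cues = out$cues, grid = out$grid),
            class = "stimulus_set")
}

#' Sample a stimulus presentation schedule
#'
#' Alternating off/on intervals with durations drawn from exponential
#' distributions with means `T_off` and `T_on`; stimulus identities are
#' uniform over the set. The schedule is truncated at the phase end.
#'
#' @param duration phase duration \[s\]
#' @param T_on,T_off mean presentation / inter-stimulus durations \[s\]
#' @param n_stimuli number of stimuli to draw identities from
#' @param seed seed
#' @return data frame with columns `stim`, `t_on`, `t_off` (times relative
#'   to phase start)
#' @export
schedule_events <- function(duration, T_on, T_off, n_stimuli, seed = 1) {
  stopifnot(duration >= 0)
  with_seed(seed, {
    stim <- integer(0); t_on <- numeric(0); t_off <- numeric(0)
    t <- 0
    repeat {
      t_start <- t + rexp(1, 1 / T_off)
      if (t_start >= duration) break
      dur <- rexp(1, 1 / T_on)
      stim <- c(stim, sample.int(n_stimuli, 1))
      t_on <- c(t_on, t_start)
      t_off <- c(t_off, min(t_start + dur, duration))
      t <- t_start + dur
      if (t >= duration) break
    }
    data.frame(stim = stim, t_on = t_on, t_off = t_off)
  })
}

#' Generate Poisson spike events for a stimulus-like population
#'
#' Per time step, each neuron spikes with probability `rate * dt`
#' (Bernoulli); members of `active_set` use `rate_active`, all others
#' `rate_bg`. This is the R-level counterpart of the drive generator built
#' into the compiled engine and is mainly used for oracles and fixtures.
#'
#' @param active_set integer indices driven at `rate_active`
#' @param rate_active,rate_bg firing rates \[Hz\]
#' @param n population size
#' @param duration length of the generated segment \[s\]
#' @param dt time step \[s\]
#' @param seed seed
#' @return data frame with `time` (end-of-step convention) and `neuron`
#' @export
poisson_drive <- function(active_set, rate_active, rate_bg, n, duration,
                          dt, seed = 1) {
  stopifnot(rate_active >= 0, rate_bg >= 0)
  if (rate_active * dt >= 1 || rate_bg * dt >= 1)
    stop("poisson_drive: rate * dt >= 1; decrease the rate or the step")
  nsteps <- round(duration / dt)
  act <- sort(unique(active_set))
  bg <- setdiff(seq_len(n), act)
  with_seed(seed, {
    times <- numeric(0); ids <- integer(0)
    for (s in seq_len(nsteps)) {
      ka <- if (length(act)) rbinom(1, length(act), rate_active * dt) else 0L
      kb <- if (length(bg)) rbinom(1, length(bg), rate_bg * dt) else 0L
      sp <- c(if (ka > 0) sample(act, ka), if (kb > 0) sample(bg, kb))
      if (length(sp)) {
        times <- c(times, rep(s * dt, length(sp)))
        ids <- c(ids, sp)
      }
    }
    data.frame(time = times, neuron = ids)
  })
}

#' Protocol schedule
#'
#' Durations and rates of the burn-in / training / consolidation / testing
#' phases. `test_times` are consolidation times (0 = immediately after
#' training) at which a testing branch is forked off; consolidation then
#' continues unperturbed on the main trajectory.
#'
#' @param T_burn,T_training,T_consolidation,T_testing phase durations \[s\]
#' @param T_on_training,T_off_training mean stimulus on/off intervals in
#'   training \[s\]
#' @param T_on_testing,T_off_testing mean cue on/off intervals in testing
#'   \[s\]
#' @param nu_bg STIM background rate outside consolidation \[Hz\]
#' @param nu_stim active-stimulus (and cue) rate \[Hz\]
#' @param nu_cons STIM background rate during consolidation \[Hz\]; set to
#'   0 in configurations where STIM is silenced during consolidation
#' @param nu_ext_cons external-population rate during consolidation \[Hz\]
#'   (external populations are silent outside consolidation)
#' @param test_times consolidation times at which recall is probed \[s\]
#' @param dt_eng engram-labeling window: length of the final stretch of
#'   training over which stimulus-evoked rates are averaged \[s\]
#' @param zeta_thr engram rate threshold \[Hz\]
#' @param bin population-activity bin width \[s\]
#' @export
protocol_schedule <- function(T_burn = 10, T_training = 150,
                              T_consolidation = 300, T_testing = 40,
                              T_on_training = 1, T_off_training = 2,
                              T_on_testing = 1, T_off_testing = 3,
                              nu_bg = 5, nu_stim = 35, nu_cons = 5,
                              nu_ext_cons = 5,
                              test_times = c(0, T_consolidation),
                              dt_eng = 100, zeta_thr = 10, bin = 10e-3) {
  stopifnot(T_burn >= 0, T_training >= 0, T_consolidation >= 0,
            T_testing >= 0)
  structure(list(T_burn = T_burn, T_training = T_training,
                 T_consolidation = T_consolidation, T_testing = T_testing,
                 T_on_training = T_on_training,
                 T_off_training = T_off_training,
                 T_on_testing = T_on_testing, T_off_testing = T_off_testing,
                 nu_bg = nu_bg, nu_stim = nu_stim, nu_cons = nu_cons,
                 nu_ext_cons = nu_ext_cons,
                 test_times = sort(unique(test_times)),
                 dt_eng = dt_eng, zeta_thr = zeta_thr, bin = bin),
            class = "protocol_schedule")
}

#' Protocol manipulation
#'
#' @param kind one of `"block-engram-output"`,
#'   `"block-inhibitory-neurons"`, `"block-inhibitory-engrams"`,
#'   `"ablate-region"`, `"ablate-plasticity-term"`, `"scale-beta"`
#' @param region target region (blocking/ablation kinds)
#' @param projection target projection (`"scale-beta"`)
#' @param term one of `"triplet"`, `"heterosynaptic"`, `"transmitter"`,
#'   `"inhibitory"` for `"ablate-plasticity-term"`
#' @param factor multiplier for `"scale-beta"`
#' @param phase when the manipulation is active: `"all"`,
#'   `"consolidation"` (applied after training/labeling) or `"testing"`
#'   (applied to the forked testing branch only)
#' @export
manipulation <- function(kind = c("block-engram-output",
                                  "block-inhibitory-neurons",
                                  "block-inhibitory-engrams",
                                  "ablate-region",
                                  "ablate-plasticity-term", "scale-beta"),
                         region = NULL, projection = NULL, term = NULL,
                         factor = NULL,
                         phase = c("consolidation", "testing", "all")) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  if (kind == "scale-beta" && (is.null(projection) || is.null(factor)))
    stop("scale-beta requires `projection` and `factor`")
  if (kind == "ablate-plasticity-term" && is.null(term))
    stop("ablate-plasticity-term requires `term`")
  if (kind %in% c("block-engram-output", "block-inhibitory-neurons",
                  "block-inhibitory-engrams", "ablate-region") &&
      is.null(region))
    stop(kind, " requires `region`")
  structure(list(kind = kind, region = region, projection = projection,
                 term = term, factor = factor, phase = phase),
            class = "manipulation")
}

#' Apply a manipulation to a built network
#'
#' Blocking kinds install per-source transmission masks (reversible);
#' `"ablate-region"` disables the region and thereby all its afferent and
#' efferent projections; `"ablate-plasticity-term"` zeroes exactly one
#' term of the long-term excitatory rule (`A`, `beta`, or `delta`) or
#' freezes inhibitory plasticity; `"scale-beta"` multiplies the
#' heterosynaptic strength of one named projection.
#'
#' Blocking the output of engram cells masks only their inter-region
#' efferent synapses: the recurrent counterparts keep transmitting, so
#' local engram dynamics are untouched. Blocking inhibitory neurons masks
#' their efferents onto both excitatory and inhibitory targets.
#'
#' @param net an `engram_network` (engine state is modified in place)
#' @param manip a [manipulation()]
#' @param labels [engram_labels()] (needed by the engram-blocking kinds)
#' @export
apply_manipulation <- function(net, manip, labels = NULL) {
  projs <- net$lowlevel$projections
  pnames <- vapply(projs, `[[`, "", "name")
  if (manip$kind == "block-engram-output") {
    if (is.null(labels)) stop("block-engram-output requires engram labels")
    cells <- sort(unique(unlist(labels$exc[[manip$region]])))
    for (p in projs) {
      if (p$src == manip$region && p$src_kind == 1L &&
          p$tgt != manip$region) {
        msk <- logical(p$n_src); msk[cells] <- TRUE
        eng_set_block(net$ptr, p$name, msk)
      }
    }
  } else if (manip$kind == "block-inhibitory-neurons") {
    for (tag in c(":IE", ":II")) {
      nm <- paste0(manip$region, tag)
      if (nm %in% pnames) {
        p <- projs[[match(nm, pnames)]]
        eng_set_block(net$ptr, nm, rep(TRUE, p$n_src))
      }
    }
  } else if (manip$kind == "block-inhibitory-engrams") {
    if (is.null(labels) || is.null(labels$inh))
      stop("block-inhibitory-engrams requires inhibitory engram labels")
    cells <- sort(unique(unlist(labels$inh[[manip$region]])))
    for (tag in c(":IE", ":II")) {
      nm <- paste0(manip$region, tag)
      if (nm %in% pnames) {
        p <- projs[[match(nm, pnames)]]
        msk <- logical(p$n_src); msk[cells] <- TRUE
        eng_set_block(net$ptr, nm, msk)
      }
    }
  } else if (manip$kind == "ablate-region") {
    eng_set_enabled(net$ptr, manip$region, FALSE)
  } else if (manip$kind == "ablate-plasticity-term") {
    for (p in projs) {
      if (manip$term == "inhibitory") {
        if (p$type == 3L) eng_set_proj_param(net$ptr, p$name, "eta_inh", 0)
      } else if (p$type == 2L) {
        par <- switch(manip$term, triplet = "A", heterosynaptic = "beta",
                      transmitter = "delta",
                      stop("unknown plasticity term: ", manip$term))
        eng_set_proj_param(net$ptr, p$name, par, 0)
      }
    }
  } else if (manip$kind == "scale-beta") {
    cur <- eng_get_proj_param(net$ptr, manip$projection, "beta")
    eng_set_proj_param(net$ptr, manip$projection, "beta",
                       cur * manip$factor)
  }
  invisible(net)
}

## drive list for one segment, given phase context
segment_drive <- function(net, phase, active = integer(0), schedule) {
  pops <- vapply(net$lowlevel$pops, `[[`, "", "name")
  ext <- setdiff(pops, "STIM")
  three_region <- length(ext) > 0
  d <- list()
  if (phase == "consolidation") {
    stim_rate <- if (three_region) 0 else schedule$nu_cons
    d$STIM <- list(active = integer(0), rate_active = 0,
                   rate_bg = stim_rate)
    for (e in ext)
      d[[e]] <- list(active = integer(0), rate_active = 0,
                     rate_bg = schedule$nu_ext_cons)
  } else {
    d$STIM <- list(active = active, rate_active = schedule$nu_stim,
                   rate_bg = schedule$nu_bg)
    for (e in ext)
      d[[e]] <- list(active = integer(0), rate_active = 0, rate_bg = 0)
  }
  d
}

## run a scheduled stimulation phase (training or testing), recording
## rasters; events carry times relative to phase start
run_stimulation_phase <- function(net, events, duration, sets, schedule,
                                  record_pops) {
  chunks <- list()
  append_r <- function(res) {
    for (nm in names(res$rasters))
      chunks[[nm]][[length(chunks[[nm]]) + 1L]] <<- res$rasters[[nm]]
  }
  t0 <- eng_time(net$ptr)
  t_cur <- 0
  rec <- list(raster = record_pops)
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    if (ev$t_on > t_cur) {
      res <- eng_run(net$ptr, ev$t_on - t_cur,
                     segment_drive(net, "stim", integer(0), schedule), rec)
      append_r(res)
    }
    res <- eng_run(net$ptr, ev$t_off - ev$t_on,
                   segment_drive(net, "stim", sets[[ev$stim]], schedule),
                   rec)
    append_r(res)
    t_cur <- ev$t_off
  }
  if (duration > t_cur) {
    res <- eng_run(net$ptr, duration - t_cur,
                   segment_drive(net, "stim", integer(0), schedule), rec)
    append_r(res)
  }
  rasters <- lapply(chunks, function(ch) list(
    time = unlist(lapply(ch, `[[`, "time"), use.names = FALSE),
    neuron = unlist(lapply(ch, `[[`, "neuron"), use.names = FALSE)))
  list(rasters = rasters, t_start = t0, t_end = eng_time(net$ptr))
}

#' Run the full burn-in / training / consolidation / testing protocol
#'
#' Executes the multi-phase protocol on a built network: burn-in under
#' background drive, training with randomly scheduled full stimuli, engram
#' labeling from the final stretch of training, then consolidation during
#' which, at each configured test time, the full simulator state is forked
#' and a testing phase with partial cues is run on the fork (consolidation
#' continues unperturbed on the main trajectory; plasticity stays on
#' everywhere, including testing branches). Manipulations are applied at
#' the start of the phase they name; `"testing"`-phase manipulations are
#' applied to each testing branch only.
#'
#' @param net an `engram_network` (modified in place; final state is the
#'   end-of-consolidation state)
#' @param stimuli a [make_stimuli()] stimulus set
#' @param schedule a [protocol_schedule()]
#' @param manipulations list of [manipulation()] objects
#' @param seed trial seed controlling event schedules and Poisson drive
#' @param record_inh also record inhibitory rasters and label inhibitory
#'   engrams
#' @param snapshot_projections projection names to snapshot at every test
#'   time (defaults to all long-term-plastic projections)
#' @param progress print per-phase progress
#' @return an object of class `engram_run` with engram labels, per-test
#'   recall rasters and metrics inputs, binned consolidation activity per
#'   ensemble, and weight snapshots
#' @export
run_protocol <- function(net, stimuli, schedule, manipulations = list(),
                         seed = 1, record_inh = TRUE,
                         snapshot_projections = NULL, progress = FALSE) {
  regions <- vapply(net$lowlevel$regions, `[[`, "", "name")
  exc_pops <- paste0(regions, ".e")
  inh_pops <- paste0(regions, ".i")
  record_pops <- c(exc_pops, if (record_inh) inh_pops)
  k <- stimuli$n_stimuli
  if (is.null(snapshot_projections)) {
    snapshot_projections <- vapply(
      Filter(function(p) p$type == 2L, net$lowlevel$projections),
      `[[`, "", "name")
  }
  eng_seed(net$ptr, seed_stream(seed, "engine-drive"))

  say <- function(...) if (progress) message(...)
  for (m in manipulations)
    if (m$phase == "all") apply_manipulation(net, m)

  ## burn-in
  say("burn-in (", schedule$T_burn, " s)")
  if (schedule$T_burn > 0)
    eng_run(net$ptr, schedule$T_burn,
            segment_drive(net, "stim", integer(0), schedule), list())

  ## training
  say("training (", schedule$T_training, " s)")
  train_events <- schedule_events(schedule$T_training,
                                  schedule$T_on_training,
                                  schedule$T_off_training, k,
                                  seed = seed_stream(seed, "train-schedule"))
  train <- run_stimulation_phase(net, train_events, schedule$T_training,
                                 stimuli$stimuli, schedule, record_pops)
  train_events_abs <- train_events
  train_events_abs$t_on <- train_events_abs$t_on + train$t_start
  train_events_abs$t_off <- train_events_abs$t_off + train$t_start

  ## engram labeling from the last dt_eng of training
  labels <- list(exc = list(), inh = if (record_inh) list() else NULL)
  for (i in seq_along(regions)) {
    rn <- regions[i]
    ne <- net$lowlevel$regions[[i]]$ne
    ni <- net$lowlevel$regions[[i]]$ni
    labels$exc[[rn]] <- label_engrams(
      train$rasters[[exc_pops[i]]], train_events_abs,
      zeta_thr = schedule$zeta_thr,
      dt_eng = min(schedule$dt_eng, schedule$T_training),
      t_end = train$t_end, n_neurons = ne)
    if (record_inh)
      labels$inh[[rn]] <- label_engrams(
        train$rasters[[inh_pops[i]]], train_events_abs,
        zeta_thr = schedule$zeta_thr,
        dt_eng = min(schedule$dt_eng, schedule$T_training),
        t_end = train$t_end, n_neurons = ni)
  }

  ## consolidation-phase manipulations
  for (m in manipulations)
    if (m$phase == "consolidation") apply_manipulation(net, m, labels)

  ## ensemble groups for binned consolidation activity
  groups <- list()
  for (i in seq_along(regions)) {
    rn <- regions[i]
    for (s in seq_len(k)) {
      idx <- labels$exc[[rn]]$ensembles[[s]]
      if (length(idx))
        groups[[paste0(rn, ".e.", s)]] <- list(pop = exc_pops[i], idx = idx)
      if (record_inh) {
        idx <- labels$inh[[rn]]$ensembles[[s]]
        if (length(idx))
          groups[[paste0(rn, ".i.", s)]] <- list(pop = inh_pops[i],
                                                 idx = idx)
      }
    }
  }

  ## consolidation with forked test branches
  test_times <- schedule$test_times
  tests <- list()
  snapshots <- list()
  bin_counts <- NULL
  bin_t0 <- eng_time(net$ptr)
  t_done <- 0
  run_test_branch <- function(label) {
    fork <- fork_network(net)
    for (m in manipulations)
      if (m$phase == "testing") apply_manipulation(fork, m, labels)
    ev <- schedule_events(schedule$T_testing, schedule$T_on_testing,
                          schedule$T_off_testing, k,
                          seed = seed_stream(seed,
                                             paste0("test-", label)))
    tb <- run_stimulation_phase(fork, ev, schedule$T_testing,
                                stimuli$cues, schedule, record_pops)
    ev_abs <- ev
    ev_abs$t_on <- ev_abs$t_on + tb$t_start
    ev_abs$t_off <- ev_abs$t_off + tb$t_start
    list(time = label, events = ev_abs, rasters = tb$rasters)
  }
  for (tt in test_times) {
    if (tt > t_done) {
      res <- eng_run(net$ptr, tt - t_done,
                     segment_drive(net, "consolidation", integer(0),
                                   schedule),
                     list(bin = schedule$bin, groups = groups))
      bin_counts <- rbind(bin_counts, res$bin_counts)
      t_done <- tt
    }
    say("test branch at consolidation time ", tt, " s")
    tests[[as.character(tt)]] <- run_test_branch(tt)
    snapshots[[as.character(tt)]] <-
      lapply(stats::setNames(nm = snapshot_projections),
             function(p) snapshot_weights(net, p))
  }
  if (schedule$T_consolidation > t_done) {
    res <- eng_run(net$ptr, schedule$T_consolidation - t_done,
                   segment_drive(net, "consolidation", integer(0),
                                 schedule),
                   list(bin = schedule$bin, groups = groups))
    bin_counts <- rbind(bin_counts, res$bin_counts)
  }

  group_sizes <- vapply(groups, function(g) length(g$idx), integer(1))
  structure(list(
    stimuli = stimuli, schedule = schedule, seed = seed,
    manipulations = manipulations,
    regions = regions, labels = labels,
    train_events = train_events_abs,
    tests = tests, snapshots = snapshots,
    consolidation = list(bin = schedule$bin, t0 = bin_t0,
                         counts = bin_counts, groups = names(groups),
                         group_sizes = group_sizes),
    net = net), class = "engram_run")
}

#' Recall metrics for every region and test time of a run
#'
#' Convenience wrapper applying [recall_metrics()] to each testing branch
#' of an [run_protocol()] result.
#'
#' @param run an `engram_run`
#' @param zeta_thr activation threshold \[Hz\]; defaults to the run's
#'   labeling threshold
#' @return a data frame keyed by region and consolidation time
#' @export
run_recall_table <- function(run, zeta_thr = NULL) {
  zt <- zeta_thr %||% run$schedule$zeta_thr
  out <- NULL
  for (tb in run$tests) {
    for (rn in run$regions) {
      if (!any(lengths(run$labels$exc[[rn]]$ensembles) > 0)) {
        warning("run_recall_table: no labeled ensembles in ", rn,
                "; region skipped", call. = FALSE)
        next
      }
      m <- recall_metrics(tb$rasters[[paste0(rn, ".e")]],
                          run$labels$exc[[rn]], tb$events, zeta_thr = zt)
      out <- rbind(out, data.frame(
        region = rn, time = tb$time, accuracy = m$accuracy,
        tpr = m$tpr, fpr = m$fpr, n_cues = m$n_cues))
    }
  }
  out
}
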