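#' @importFrom utils modifyList write.table read.table packageVersion
NULL

#' Write / read spike event tables
#'
#' Events are stored as tab-separated text with a small commented header
#' (population, dt, duration) and columns `time` \[s\] and `neuron`
#' (1-based). Rows must be sorted by time; the reader rejects files that
#' are not, naming the offending line.
#'
#' @param table data frame (or raster list) with `time` and `neuron`
#' @param path output file
#' @param population population name recorded in the header
#' @param dt,duration metadata recorded in the header
#' @export
write_events <- function(table, path, population = "pop", dt = NA,
                         duration = NA) {
  r <- as_raster(table)
  if (is.unsorted(r$time)) stop("write_events: events must be time-sorted")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# population=", population),
               paste0("# dt=", dt),
               paste0("# duration=", duration),
               "time\tneuron"), con)
  if (length(r$time))
    write.table(data.frame(time = r$time, neuron = r$neuron), con,
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "="), `[`, 2)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (nrow(df) && is.unsorted(df$time)) {
    bad <- which(diff(df$time) < 0)[1] + 1L
    stop("read_events: events out of order at data line ", bad)
  }
  attr(df, "population") <- meta[[1]][1]
  attr(df, "dt") <- suppressWarnings(as.numeric(meta[[2]][1]))
  attr(df, "duration") <- suppressWarnings(as.numeric(meta[[3]][1]))
  df
}

#' Write projection weights as MatrixMarket coordinate files
#'
#' One `.mtx` file per projection (1-based coordinates per the format
#' standard); consolidating projections get a companion
#' `<name>_ref.mtx` with the reference weights.
#'
#' @param net an `engram_network`
#' @param projection projection name
#' @param dir output directory
#' @return the main file path, invisibly
#' @export
write_weights_mtx <- function(net, projection, dir = ".") {
  tb <- snapshot_weights(net, projection)
  safe <- gsub("[^A-Za-z0-9_]+", "_", projection)
  p <- net$lowlevel$projections[[
    match(projection, projection_names(net))]]
  path <- file.path(dir, paste0(safe, ".mtx"))
  m <- Matrix::sparseMatrix(i = tb$tgt, j = tb$src, x = tb$w,
                            dims = c(p$n_tgt, p$n_src))
  Matrix::writeMM(m, path)
  if (!is.null(tb$w_tilde)) {
    mr <- Matrix::sparseMatrix(i = tb$tgt, j = tb$src, x = tb$w_tilde,
                               dims = c(p$n_tgt, p$n_src))
    Matrix::writeMM(mr, file.path(dir, paste0(safe, "_ref.mtx")))
  }
  invisible(path)
}

#' Run manifest
#'
#' A structured record sufficient to reproduce a run on the same build:
#' resolved configuration, master and derived seeds, and the artifact
#' inventory.
#'
#' @param run an `engram_run`
#' @param preset optional preset name used to build the network
#' @param scale scale tag (`"desk"` or `"paper"`)
#' @export
run_manifest <- function(run, preset = NULL, scale = "desk") {
  list(
    package_version = as.character(packageVersion("engramsim")),
    preset = preset, scale = scale,
    seed = run$seed,
    derived_seeds = list(
      engine_drive = seed_stream(run$seed, "engine-drive"),
      train_schedule = seed_stream(run$seed, "train-schedule")),
    schedule = unclass(run$schedule),
    stimuli = list(kind = run$stimuli$kind, N_stim = run$stimuli$N_stim,
                   n_stimuli = run$stimuli$n_stimuli),
    manipulations = lapply(run$manipulations, unclass),
    regions = run$regions,
    ensembles = lapply(run$labels$exc, function(l)
      vapply(l$ensembles, length, integer(1))))
}

#' Write run artifacts to a directory
#'
#' Writes the manifest (JSON), the recall-metric table (TSV), the training
#' event schedule (TSV), and weight snapshots (MatrixMarket) of the
#' long-term-plastic projections at the final state.
#'
#' @param run an `engram_run`
#' @param dir output directory (created if missing)
#' @inheritParams run_manifest
#' @export
write_run <- function(run, dir, preset = NULL, scale = "desk") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run_manifest(run, preset, scale),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(run_recall_table(run), file.path(dir, "recall_metrics.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(run$train_events, file.path(dir, "train_events.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (p in projection_names(run$net)) {
    pr <- run$net$lowlevel$projections[[
      match(p, projection_names(run$net))]]
    if (pr$type == 2L) write_weights_mtx(run$net, p, dir)
  }
  invisible(dir)
}

config_keys <- c("preset", "scale", "seed", "network", "schedule",
                 "manipulations")

#' Load a run configuration
#'
#' YAML configuration with preset inheritance: `preset` and `scale` select
#' a [network_preset()]; `network` and `schedule` supply key overrides;
#' `manipulations` lists manipulation descriptions. Unknown keys are
#' rejected with the offending path. The resolved network spec passes the
#' region-ordering validation unless the network overrides set
#' `allow_unordered`.
#'
#' @param path YAML file
#' @return list with `spec` (a [network_spec()]), `schedule`
#'   (a [protocol_schedule()]), `manipulations`, `seed`, `preset`, `scale`
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  preset <- cfg$preset %||% "two-region"
  scale <- cfg$scale %||% "desk"
  seed <- cfg$seed %||% 1L
  spec <- do.call(network_preset,
                  c(list(name = preset, scale = scale, seed = seed),
                    cfg$network %||% list()))
  sk <- setdiff(names(cfg$schedule %||% list()),
                names(formals(protocol_schedule)))
  if (length(sk))
    stop("load_config: unknown schedule key(s): schedule.",
         paste(sk, collapse = ", schedule."))
  schedule <- do.call(protocol_preset,
                      c(list(name = preset, scale = scale),
                        cfg$schedule %||% list()))
  manips <- lapply(cfg$manipulations %||% list(), function(m)
    do.call(manipulation, m))
  list(spec = spec, schedule = schedule, manipulations = manips,
       seed = seed, preset = preset, scale = scale)
}

#' Deterministic test fixtures
#'
#' `"micro"` is a two-region toy (6 excitatory / 2 inhibitory neurons per
#' region, 12 stimulus cells, dense connectivity) for step-for-step oracle
#' comparisons; `"small"` is the desk-scale two-region preset with
#' minutes-scale phases used by the property and acceptance suites.
#'
#' @param name `"micro"` or `"small"`
#' @param seed master seed
#' @return list with `spec` (a [network_spec()]), `stimuli`, `schedule`
#' @export
make_fixture <- function(name = c("micro", "small"), seed = 1) {
  name <- match.arg(name)
  if (name == "micro") {
    reg <- function(nm, eta)
      region_spec(nm, N_exc = 6, N_inh = 2, eps_rec = 0.6,
                  eta_exc = eta, eta_inh = eta * 1e-3,
                  tau_cons = 5, target_rate = 5)
    spec <- network_spec(
      regions = list(reg("HPC", 2e-3), reg("CTX", 5e-4)),
      projections = list(
        projection_spec("STIM", "HPC", eps = 0.6, w0 = 1.2,
                        tau_cons = 50),
        projection_spec("STIM", "CTX", eps = 0.6, w0 = 1.2)),
      N_stim = 12, seed = seed, dt = 1e-4, dt_long = 0.05,
      global_plasticity = list(tau_d = 0.05))
    stimuli <- make_stimuli("random-nonoverlapping", 12, 4,
                            seed = seed_stream(seed, "stimuli"))
    schedule <- protocol_schedule(T_burn = 0.05, T_training = 3,
                                  T_consolidation = 0.2, T_testing = 1,
                                  T_on_training = 0.1,
                                  T_off_training = 0.05,
                                  T_on_testing = 0.1,
                                  T_off_testing = 0.05,
                                  nu_bg = 10, nu_stim = 80,
                                  zeta_thr = 2,
                                  dt_eng = 3, test_times = 0)
  } else {
    spec <- network_preset("two-region", scale = "desk", seed = seed)
    stimuli <- make_stimuli("random-nonoverlapping", spec$N_stim, 4,
                            seed = seed_stream(seed, "stimuli"))
    schedule <- protocol_preset("two-region", scale = "desk")
  }
  list(spec = spec, stimuli = stimuli, schedule = schedule)
}
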