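#' @importFrom stats rbinom runif
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package internals do not
#' disturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Deterministic 31-bit hash mixing the master seed with a component name,
#' so that connectivity, stimulus, drive and bootstrap randomness come from
#' independent streams and changing one component's draws does not perturb
#' the others.
#'
#' @param master integer master seed
#' @param name component name
#' @return an integer seed in `[0, 2^31)`
#' @export
seed_stream <- function(master, name) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Region specification
#'
#' Describes one recurrently connected region: population sizes, recurrent
#' connectivity, initial weights and the region-level plasticity parameter
#' set. Plasticity roles follow fixed conventions: recurrent E->E synapses
#' have short- plus long-term plasticity, E->I only short-term plasticity,
#' I->E inhibitory plasticity, and I->I synapses are static.
#'
#' @param name region identifier (e.g. `"HPC"`)
#' @param N_exc,N_inh excitatory/inhibitory neuron counts
#' @param eps_rec recurrent connection probability, in (0, 1\]
#' @param w_EE,w_EI,w_IE,w_II initial weight scales (each synapse drawn
#'   uniformly in `[0.5, 1.5] * w`)
#' @param eta_exc excitatory learning rate of the region
#' @param eta_inh inhibitory learning rate
#' @param A,beta,delta triplet LTP rate, heterosynaptic strength and
#'   transmitter-induced strength for the recurrent E->E projection
#' @param tau_cons consolidation time constant of recurrent E->E \[s\]
#' @param target_rate inhibitory-plasticity target rate \[Hz\]; converted
#'   internally to the secreted-factor target
#'   `gamma = N_exc * target_rate * tau_H`
#' @param tau_H secreted-factor time constant \[s\]
#' @param w_max_exc,w_max_inh upper weight bounds
#' @param neuron a [neuron_params()] object
#' @export
region_spec <- function(name, N_exc = 512, N_inh = 128, eps_rec = 0.1,
                        w_EE = 0.2, w_EI = 0.2, w_IE = 0.6, w_II = 0.6,
                        eta_exc = 5e-4, eta_inh = 1e-5,
                        A = 1, beta = 0.02, delta = 2e-5,
                        tau_cons = 150, target_rate = 3, tau_H = 10,
                        w_max_exc = 5, w_max_inh = 10,
                        neuron = neuron_params()) {
  stopifnot(N_exc > 0, N_inh > 0, eps_rec > 0, eps_rec <= 1)
  structure(list(name = name, N_exc = as.integer(N_exc),
                 N_inh = as.integer(N_inh),
                 eps_rec = eps_rec, w_EE = w_EE, w_EI = w_EI,
                 w_IE = w_IE, w_II = w_II,
                 eta_exc = eta_exc, eta_inh = eta_inh, A = A, beta = beta,
                 delta = delta, tau_cons = tau_cons,
                 target_rate = target_rate, tau_H = tau_H,
                 w_max_exc = w_max_exc, w_max_inh = w_max_inh,
                 neuron = neuron), class = "region_spec")
}

#' Inter-population projection specification
#'
#' Projections run from excitatory (or Poisson source) populations onto
#' excitatory neurons of the target region.
#'
#' @param source source population: `"STIM"`, an external population name,
#'   or a region name (meaning its excitatory cells)
#' @param target target region name
#' @param kind `"random"` (i.i.d. Bernoulli connectivity at probability
#'   `eps`) or `"circular"` (randomly centred circular receptive fields of
#'   radius `R` on the source grid)
#' @param eps connection probability for `kind = "random"`
#' @param R receptive-field radius in grid units for `kind = "circular"`
#' @param w0 initial weight scale (synapses drawn uniformly in
#'   `[0.5, 1.5] * w0`)
#' @param plasticity `"static"`, `"stp"`, or `"stp+longterm"`
#' @param eta,A,beta,delta,tau_cons optional overrides of the long-term
#'   rule parameters for this projection (defaults inherit from the target
#'   region)
#' @param w_max optional upper weight bound override
#' @export
projection_spec <- function(source, target, kind = c("random", "circular"),
                            eps = 0.1, R = 4, w0 = 0.2,
                            plasticity = c("stp+longterm", "stp", "static"),
                            eta = NULL, A = NULL, beta = NULL, delta = NULL,
                            tau_cons = NULL, w_max = NULL) {
  structure(list(source = source, target = target,
                 kind = match.arg(kind), eps = eps, R = R, w0 = w0,
                 plasticity = match.arg(plasticity),
                 eta = eta, A = A, beta = beta, delta = delta,
                 tau_cons = tau_cons, w_max = w_max),
            class = "projection_spec")
}

#' Network specification
#'
#' @param regions list of [region_spec()] objects
#' @param projections list of [projection_spec()] objects
#' @param N_stim stimulus population size (a square number if grid
#'   geometry is used)
#' @param ext named integer vector of external Poisson population sizes,
#'   keyed by the region they drive (e.g. `c(HPC = 1024, CTX = 1024)`)
#' @param ext_eps,ext_w connectivity probability and weight of external
#'   drive projections (static)
#' @param seed master seed; all connectivity and drive randomness derives
#'   from it through named streams
#' @param dt integration time step \[s\]
#' @param dt_long consolidation step for reference weights \[s\]
#' @param exact_decay use exact exponential conductance decay instead of
#'   forward Euler
#' @param global_plasticity list of shared plasticity constants (trace
#'   time constants, short-term plasticity parameters, double-well `P` and
#'   `w_P`, `tau_hom`, `tau_istdp`)
#' @param allow_unordered skip the region-ordering validation (learning
#'   rates and consolidation timescales)
#' @export
network_spec <- function(regions, projections, N_stim = 1024,
                         ext = integer(0), ext_eps = 0.1, ext_w = 0.2,
                         seed = 1L, dt = 1e-4, dt_long = 1.2,
                         exact_decay = FALSE,
                         global_plasticity = list(),
                         allow_unordered = FALSE) {
  gp <- utils::modifyList(list(
    tau_plus = 20e-3, tau_minus = 20e-3, tau_slow = 100e-3,
    tau_ht = 100e-3, tau_hom = 10, tau_istdp = 20e-3,
    U_stp = 0.2, tau_d = 0.2, tau_f = 0.6, P = 20, w_P = 0.5),
    global_plasticity)
  spec <- structure(list(
    regions = regions, projections = projections,
    N_stim = as.integer(N_stim), ext = ext,
    ext_eps = ext_eps, ext_w = ext_w,
    seed = as.integer(seed), dt = dt, dt_long = dt_long,
    exact_decay = exact_decay, global_plasticity = gp,
    allow_unordered = allow_unordered), class = "network_spec")
  validate_network_spec(spec)
  spec
}

#' @rdname network_spec
#' @param spec a `network_spec`
#' @export
validate_network_spec <- function(spec) {
  rn <- vapply(spec$regions, `[[`, "", "name")
  if (anyDuplicated(rn)) stop("network_spec: duplicate region names")
  srcs <- c("STIM", names(spec$ext), rn)
  for (p in spec$projections) {
    if (!(p$source %in% srcs))
      stop("network_spec: unresolved projection source '", p$source, "'")
    if (!(p$target %in% rn))
      stop("network_spec: unresolved projection target '", p$target, "'")
  }
  if (!spec$allow_unordered && all(c("HPC", "CTX") %in% rn)) {
    hpc <- spec$regions[[match("HPC", rn)]]
    ctx <- spec$regions[[match("CTX", rn)]]
    if (!(hpc$eta_exc > ctx$eta_exc && hpc$eta_inh > ctx$eta_inh))
      stop("network_spec: presets require eta_hpc > eta_ctx for both ",
           "excitatory and inhibitory learning rates ",
           "(set allow_unordered = TRUE to override)")
    sh <- Filter(function(p) p$source == "STIM" && p$target == "HPC" &&
                   p$plasticity == "stp+longterm", spec$projections)
    if (length(sh)) {
      tc_sh <- sh[[1]]$tau_cons %||% hpc$tau_cons
      others <- c(
        vapply(spec$regions, `[[`, 0, "tau_cons"),
        unlist(lapply(spec$projections, function(p) {
          if (p$plasticity == "stp+longterm" &&
              !(p$source == "STIM" && p$target == "HPC"))
            p$tau_cons %||% spec$regions[[match(p$target, rn)]]$tau_cons
          else NULL
        })))
      others <- others[is.finite(others)]
      if (length(others) && !(tc_sh > max(others)))
        stop("network_spec: presets require the STIM->HPC consolidation ",
             "time constant to exceed all other excitatory tau_cons ",
             "(set allow_unordered = TRUE to override)")
    }
  }
  invisible(spec)
}

## draw i.i.d. Bernoulli connectivity; excludes self-connections when the
## source and target populations coincide
draw_random_edges <- function(n_src, n_tgt, eps, recurrent = FALSE) {
  src <- integer(0); tgt <- integer(0)
  for (j in seq_len(n_src)) {
    cand <- if (recurrent) seq_len(n_tgt)[-j] else seq_len(n_tgt)
    k <- rbinom(1, length(cand), eps)
    if (k > 0) {
      t_j <- sort(sample(cand, k))
      src <- c(src, rep(j, k)); tgt <- c(tgt, t_j)
    }
  }
  list(src = src, tgt = tgt)
}

#' Randomly centred circular receptive fields on a source grid
#'
#' Each target neuron receives input from every source cell whose
#' Euclidean distance (in grid units) from a uniformly drawn centre cell
#' is at most `R`. The source population is laid out on a `side x side`
#' grid in row-major order.
#'
#' @param side grid side length (source population size is `side^2`)
#' @param n_target number of target neurons
#' @param R receptive-field radius in grid units (`R = 0` connects each
#'   target to exactly its centre cell)
#' @param seed optional seed for the centre draws
#' @return list with `src`, `tgt` edge vectors and the drawn `centers`
#'   (matrix of row/col)
#' @export
build_circular_receptive_fields <- function(side, n_target, R, seed = NULL) {
  stopifnot(R >= 0, side >= 1, n_target >= 1)
  if (R > side * sqrt(2))
    warning("receptive-field radius exceeds the grid diagonal; ",
            "fields cover the full grid")
  run <- function() {
    offs <- expand.grid(dr = -floor(R):floor(R), dc = -floor(R):floor(R))
    offs <- offs[offs$dr^2 + offs$dc^2 <= R^2, , drop = FALSE]
    ctr_r <- sample.int(side, n_target, replace = TRUE)
    ctr_c <- sample.int(side, n_target, replace = TRUE)
    src <- integer(0); tgt <- integer(0)
    for (i in seq_len(n_target)) {
      rr <- ctr_r[i] + offs$dr
      cc <- ctr_c[i] + offs$dc
      ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
      cells <- as.integer((rr[ok] - 1) * side + cc[ok])
      src <- c(src, sort(cells)); tgt <- c(tgt, rep(i, sum(ok)))
    }
    list(src = src, tgt = tgt, centers = cbind(row = ctr_r, col = ctr_c))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

proj_type_code <- function(plasticity) {
  switch(plasticity, static = 0L, stp = 1L, `stp+longterm` = 2L,
         inh = 3L, stop("unknown plasticity kind"))
}

#' Build a simulator instance from a network specification
#'
#' Draws all connectivity and initial weights deterministically from the
#' spec's master seed (through named sub-streams), assembles the low-level
#' network description, and instantiates the compiled engine. Reference
#' weights of consolidating projections are initialised at the initial
#' weights.
#'
#' @param spec a [network_spec()]
#' @return an object of class `engram_network` wrapping the engine handle;
#'   element `lowlevel` carries the full resolved description (also
#'   consumed by [reference_engine()])
#' @export
build_network <- function(spec) {
  validate_network_spec(spec)
  rn <- vapply(spec$regions, `[[`, "", "name")
  pops <- c(list(list(name = "STIM", n = spec$N_stim)),
            lapply(seq_along(spec$ext), function(i)
              list(name = paste0("EXT_", names(spec$ext)[i]),
                   n = as.integer(spec$ext[[i]]))))
  regions <- lapply(spec$regions, function(r)
    list(name = r$name, ne = r$N_exc, ni = r$N_inh,
         neuron = unclass(r$neuron), tau_H = r$tau_H))

  conn_seed <- seed_stream(spec$seed, "connectivity")
  projections <- with_seed(conn_seed, {
    out <- list()
    ## feedforward projections, in spec order
    for (p in spec$projections) {
      reg <- spec$regions[[match(p$target, rn)]]
      n_src <- if (p$source == "STIM") spec$N_stim
      else if (p$source %in% names(spec$ext)) spec$ext[[p$source]]
      else spec$regions[[match(p$source, rn)]]$N_exc
      src_name <- if (p$source %in% names(spec$ext))
        paste0("EXT_", p$source) else p$source
      if (p$kind == "circular") {
        side <- round(sqrt(n_src))
        if (side^2 != n_src)
          stop("circular receptive fields require a square source grid")
        ed <- build_circular_receptive_fields(side, reg$N_exc, p$R)
      } else {
        ed <- draw_random_edges(n_src, reg$N_exc, p$eps)
      }
      m <- length(ed$src)
      w <- runif(m, 0.5, 1.5) * p$w0
      type <- proj_type_code(p$plasticity)
      out[[paste0(p$source, "->", p$target)]] <- list(
        name = paste0(p$source, "->", p$target),
        src = src_name, tgt = p$target,
        src_kind = if (src_name %in% c("STIM") ||
                       startsWith(src_name, "EXT_")) 0L else 1L,
        tgt_part = 1L, n_src = n_src, n_tgt = reg$N_exc,
        src_id = ed$src, tgt_id = ed$tgt, w = w,
        w_tilde = if (type == 2L) w else NULL, type = type,
        eta = p$eta %||% reg$eta_exc, A = p$A %||% reg$A,
        beta = p$beta %||% reg$beta, delta = p$delta %||% reg$delta,
        tau_cons = p$tau_cons %||% reg$tau_cons,
        eta_inh = 0, gamma = 0,
        w_min = 0, w_max = p$w_max %||% reg$w_max_exc)
    }
    ## external drive projections (static, random-uniform)
    for (nm in names(spec$ext)) {
      reg <- spec$regions[[match(nm, rn)]]
      ed <- draw_random_edges(spec$ext[[nm]], reg$N_exc, spec$ext_eps)
      out[[paste0("EXT_", nm, "->", nm)]] <- list(
        name = paste0("EXT_", nm, "->", nm),
        src = paste0("EXT_", nm), tgt = nm, src_kind = 0L, tgt_part = 1L,
        n_src = spec$ext[[nm]], n_tgt = reg$N_exc,
        src_id = ed$src, tgt_id = ed$tgt,
        w = runif(length(ed$src), 0.5, 1.5) * spec$ext_w,
        type = 0L, eta = 0, A = 0, beta = 0, delta = 0, tau_cons = 0,
        eta_inh = 0, gamma = 0, w_min = 0, w_max = reg$w_max_exc)
    }
    ## recurrent projections per region: EE, EI, IE, II
    for (r in spec$regions) {
      gamma <- r$N_exc * r$target_rate * r$tau_H
      mk <- function(tag, n_src, n_tgt, src_kind, tgt_part, w0, type,
                     recurrent, eta = 0, A = 0, beta = 0, delta = 0,
                     tau_cons = 0, eta_inh = 0, gm = 0, w_max) {
        ed <- draw_random_edges(n_src, n_tgt, r$eps_rec,
                                recurrent = recurrent)
        list(name = paste0(r$name, ":", tag), src = r$name, tgt = r$name,
             src_kind = src_kind, tgt_part = tgt_part,
             n_src = n_src, n_tgt = n_tgt,
             src_id = ed$src, tgt_id = ed$tgt,
             w = (w_draw <- runif(length(ed$src), 0.5, 1.5) * w0),
             w_tilde = if (type == 2L) w_draw else NULL,
             type = type, eta = eta, A = A, beta = beta, delta = delta,
             tau_cons = tau_cons, eta_inh = eta_inh, gamma = gm,
             w_min = 0, w_max = w_max)
      }
      out[[paste0(r$name, ":EE")]] <- mk(
        "EE", r$N_exc, r$N_exc, 1L, 1L, r$w_EE, 2L, recurrent = TRUE,
        eta = r$eta_exc, A = r$A, beta = r$beta, delta = r$delta,
        tau_cons = r$tau_cons, w_max = r$w_max_exc)
      out[[paste0(r$name, ":EI")]] <- mk(
        "EI", r$N_exc, r$N_inh, 1L, 2L, r$w_EI, 1L, recurrent = FALSE,
        w_max = r$w_max_exc)
      out[[paste0(r$name, ":IE")]] <- mk(
        "IE", r$N_inh, r$N_exc, 2L, 1L, r$w_IE, 3L, recurrent = FALSE,
        eta_inh = r$eta_inh, gm = gamma, w_max = r$w_max_inh)
      out[[paste0(r$name, ":II")]] <- mk(
        "II", r$N_inh, r$N_inh, 2L, 2L, r$w_II, 0L, recurrent = TRUE,
        w_max = r$w_max_inh)
    }
    out
  })

  lowlevel <- list(
    dt = spec$dt, dt_long = spec$dt_long, exact_decay = spec$exact_decay,
    seed = seed_stream(spec$seed, "drive"),
    global_plasticity = spec$global_plasticity,
    pops = pops, regions = regions, projections = unname(projections))
  net <- structure(list(spec = spec, lowlevel = lowlevel,
                        ptr = eng_build(lowlevel)),
                   class = "engram_network")
  net
}

#' @export
print.engram_network <- function(x, ...) {
  rn <- vapply(x$lowlevel$regions, `[[`, "", "name")
  cat("<engram_network> regions:", paste(rn, collapse = ", "),
      "| projections:", length(x$lowlevel$projections),
      "| t =", format(eng_time(x$ptr)), "s\n")
  invisible(x)
}

#' Fork a network (independent deep copy of the full simulator state)
#'
#' Used by the protocol driver to run a testing branch at a given
#' consolidation time without perturbing the continuing consolidation
#' trajectory.
#'
#' @param net an `engram_network`
#' @return an independent copy
#' @export
fork_network <- function(net) {
  net$ptr <- eng_clone(net$ptr)
  net
}

#' Snapshot and restore projection weights
#'
#' `snapshot_weights` extracts the sparse triplet table (source, target,
#' weight, and reference weight where present) of one projection;
#' `restore_weights` writes a compatible table back. The round trip is
#' lossless.
#'
#' @param net an `engram_network`
#' @param projection projection name (e.g. `"STIM->HPC"`, `"HPC:EE"`)
#' @return a `data.frame` with columns `src`, `tgt`, `w` and optionally
#'   `w_tilde`
#' @export
snapshot_weights <- function(net, projection) {
  wl <- eng_get_weights(net$ptr, projection)
  df <- data.frame(src = wl$src, tgt = wl$tgt, w = wl$w)
  if (!is.null(wl$w_tilde)) df$w_tilde <- wl$w_tilde
  df
}

#' @rdname snapshot_weights
#' @param table a data frame as returned by `snapshot_weights`
#' @export
restore_weights <- function(net, projection, table) {
  cur <- eng_get_weights(net$ptr, projection)
  if (nrow(table) != length(cur$w))
    stop("restore_weights: synapse count mismatch for ", projection)
  ord_cur <- order(cur$src, cur$tgt)
  ord_new <- order(table$src, table$tgt)
  if (!identical(cur$src[ord_cur], as.integer(table$src[ord_new])) ||
      !identical(cur$tgt[ord_cur], as.integer(table$tgt[ord_new])))
    stop("restore_weights: connectivity mismatch for ", projection)
  w <- numeric(length(cur$w))
  w[ord_cur] <- table$w[ord_new]
  wt <- NULL
  if (!is.null(table$w_tilde)) {
    wt <- numeric(length(cur$w))
    wt[ord_cur] <- table$w_tilde[ord_new]
  }
  eng_set_weights(net$ptr, projection, w, wt)
  invisible(net)
}

#' Projection names of a built network
#' @param net an `engram_network`
#' @export
projection_names <- function(net) {
  vapply(net$lowlevel$projections, `[[`, "", "name")
}
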