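# Exact stochastic simulation (Gillespie) of the copy-number + occupancy
# jump process. The inner loop lives in src/ssa.cpp; randomness comes from
# R's RNG so a seed makes every trajectory bitwise reproducible.

#' Simulate a trajectory of the network
#'
#' Exact SSA over synthesis, degradation, binding (sequestering `m` source
#' copies) and unbinding reactions. Optionally accumulates an exact
#' time-weighted 3D occupancy histogram over three marginal species while it
#' runs; this is what the landscape estimate uses, since dwell-time weighting
#' resolves probabilities far below what thinned records can.
#'
#' @param network a `network_spec`.
#' @param t_max simulated time horizon (> 0).
#' @param seed integer seed; same seed, same trajectory.
#' @param record_every record the state at this time spacing (0 or `Inf`
#'   disables records; the occupancy histogram is unaffected).
#' @param burn_in initial time span excluded from the occupancy histogram.
#' @param init named integer vector of initial copy numbers (default all 0,
#'   all sites unbound).
#' @param occupancy_axes three node names to marginalize onto (e.g.
#'   `c("P53","ZEB","OCT4")`), or `NULL` for no histogram.
#' @param bin_width copy-number bin width of the histogram (default 5).
#' @param n_bins bins per axis (default 160, covering 0..800 copies at the
#'   default bin width).
#' @param max_events hard cap on reaction events.
#' @return A `trajectory` object: `records` (data.frame time + one column per
#'   species, or NULL), `occupancy` (3D dwell-time array or NULL, with
#'   attributes `axes`, `bin_width`), `seed`, `burn_in`, `t_max`, `events`,
#'   `final` state.
#' @export
simulate_grn <- function(network, t_max, seed, record_every = 1,
                         burn_in = 0, init = NULL,
                         occupancy_axes = NULL, bin_width = 5, n_bins = 160,
                         max_events = Inf) {
  stopifnot(t_max > 0)
  nm <- node_names(network)
  n0 <- integer(length(nm))
  names(n0) <- nm
  if (!is.null(init)) {
    stopifnot(all(names(init) %in% nm))
    n0[names(init)] <- as.integer(init)
  }
  axes_idx <- integer(0)
  if (!is.null(occupancy_axes)) {
    stopifnot(length(occupancy_axes) == 3, all(occupancy_axes %in% nm))
    axes_idx <- match(occupancy_axes, nm) - 1L
  }
  mod <- pack_model(network)
  set.seed(as.integer(seed))
  res <- .ssa_run_cpp(mod, n0, integer(length(network$regulations)),
                      as.numeric(t_max), as.numeric(burn_in),
                      as.numeric(record_every),
                      axes_idx, as.numeric(bin_width), as.integer(n_bins),
                      logical(0), as.numeric(max_events))
  records <- NULL
  if (!is.null(res$records)) {
    records <- as.data.frame(res$records)
    colnames(records) <- c("time", nm)
  }
  occ <- res$occupancy
  if (!is.null(occ)) {
    attr(occ, "axes") <- occupancy_axes
    attr(occ, "bin_width") <- bin_width
  }
  structure(list(records = records, occupancy = occ,
                 seed = as.integer(seed), burn_in = burn_in, t_max = t_max,
                 events = res$events, absorbed = res$absorbed,
                 final = list(copy_numbers = setNames(res$n_final, nm),
                              bound = res$bound_final)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: t_max = %g, %.3g events, seed = %d%s\n",
              x$t_max, x$events, x$seed,
              if (!is.null(x$records)) sprintf(", %d records", nrow(x$records)) else ""))
  invisible(x)
}

#' Ensemble of independent trajectories
#'
#' Member seeds are drawn deterministically from the master seed, so the
#' whole ensemble is reproducible and members are independent streams.
#'
#' @inheritParams simulate_grn
#' @param n_runs number of trajectories (>= 1).
#' @param inits optional list of named initial copy-number vectors, recycled
#'   over runs (e.g. [dispersed_inits()] for multistable systems whose basins
#'   a single start cannot reach in feasible time).
#' @param ... forwarded to [simulate_grn()].
#' @return List of `trajectory` objects (class `trajectory_ensemble`).
#' @export
ensemble_grn <- function(network, n_runs, t_max, burn_in = 0.1 * t_max,
                         seed = 1, inits = NULL, ...) {
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(seed, n_runs)
  out <- lapply(seq_len(n_runs), function(i)
    simulate_grn(network, t_max = t_max, seed = seeds[i], burn_in = burn_in,
                 init = if (is.null(inits)) NULL
                        else inits[[(i - 1) %% length(inits) + 1]], ...))
  class(out) <- c("trajectory_ensemble", "list")
  out
}

#' Stratified initial conditions over three marker axes
#'
#' The default circuit is deeply metastable: from a single start, desk-scale
#' trajectories never cross the higher barriers, so pooled occupancy misses
#' whole basins. This helper builds the 8 low/high corners of the marker
#' axes plus an all-intermediate point; non-marker species start at their
#' basal level `g0/k` and relax within ~1/k. Pooled dwell time from these
#' starts discovers every attractor; cross-basin weights converge to the
#' stationary law only in the long-time limit (see the methods vignette).
#'
#' @param network a `network_spec`.
#' @param axes marker node names (default P53, ZEB, OCT4).
#' @param levels two copy numbers for the low/high corners.
#' @param mid copy number of the all-intermediate start.
#' @return List of named integer vectors.
#' @export
dispersed_inits <- function(network, axes = c("P53", "ZEB", "OCT4"),
                            levels = c(30, 350), mid = 180) {
  nm <- node_names(network)
  stopifnot(all(axes %in% nm))
  basal <- setNames(vapply(network$nodes, function(n) n$g0 / n$k, 0), nm)
  corners <- expand.grid(rep(list(levels), length(axes)))
  inits <- lapply(seq_len(nrow(corners)), function(i) {
    x <- round(basal)
    x[axes] <- as.numeric(corners[i, ])
    x
  })
  x <- round(basal); x[axes] <- mid
  c(inits, list(x))
}

#' Derive independent child seeds from a master seed
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' One Gillespie step (reference implementation)
#'
#' A plain-R single step used in tests and teaching: computes the propensity
#' vector, draws an exponential waiting time and picks a reaction. The
#' production path is the compiled loop in [simulate_grn()]; both share the
#' rate laws of the model module.
#'
#' @param state list with `copy_numbers` (named integer) and `bound`
#'   (integer vector over regulations).
#' @param network a `network_spec`.
#' @return list(next_state, waiting_time, event) or an `absorbed = TRUE`
#'   marker when the total propensity is zero.
#' @export
ssa_step <- function(state, network) {
  pv <- propensity_vector(state, network)
  total <- sum(pv$rate)
  if (total <= 0) return(list(absorbed = TRUE))
  wt <- stats::rexp(1, total)
  i <- sample.int(nrow(pv), 1, prob = pv$rate)
  ev <- pv[i, ]
  st <- state
  nm <- node_names(network)
  if (ev$kind == "synthesis") {
    st$copy_numbers[ev$node] <- st$copy_numbers[ev$node] + 1
  } else if (ev$kind == "degradation") {
    st$copy_numbers[ev$node] <- st$copy_numbers[ev$node] - 1
  } else {
    r <- network$regulations[[ev$site]]
    if (ev$kind == "binding") {
      st$copy_numbers[r$source] <- st$copy_numbers[r$source] - r$m
      st$bound[ev$site] <- 1L
    } else {
      st$copy_numbers[r$source] <- st$copy_numbers[r$source] + r$m
      st$bound[ev$site] <- 0L
    }
  }
  list(next_state = st, waiting_time = wt, event = ev, absorbed = FALSE)
}

#' Propensity vector of a system state
#'
#' One row per possible reaction: synthesis per gene at the
#' occupancy-dependent rate, degradation per species at `k * n` (free,
#' unsequestered copies only), binding per unbound site at the mass-action
#' law, unbinding per bound site at `f`.
#'
#' @inheritParams ssa_step
#' @return data.frame with columns kind, node, site, rate.
#' @export
propensity_vector <- function(state, network) {
  nm <- node_names(network)
  regs <- network$regulations
  n <- state$copy_numbers[nm]
  bound <- state$bound
  rows <- list()
  for (j in seq_along(nm)) {
    tgt_sites <- which(vapply(regs, function(r) r$target == nm[j], TRUE))
    occ <- if (length(tgt_sites)) bound[tgt_sites] else logical(0)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "synthesis", node = nm[j], site = NA_integer_,
      rate = synthesis_rate(network, nm[j], occ))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "degradation", node = nm[j], site = NA_integer_,
      rate = network$nodes[[j]]$k * n[j])
  }
  for (s in seq_along(regs)) {
    r <- regs[[s]]
    rows[[length(rows) + 1]] <- data.frame(
      kind = "binding", node = r$source, site = s,
      rate = if (bound[s]) 0 else binding_propensity(r, n[r$source]))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "unbinding", node = r$source, site = s,
      rate = if (bound[s]) r$f else 0)
  }
  do.call(rbind, rows)
}

#' First-passage simulation into a voxel target set
#'
#' Runs the SSA from a given initial state until the (axes) marginal enters
#' the target voxel mask, or until `max_events` is exhausted (censored).
#'
#' @param network a `network_spec`.
#' @param init named integer vector of initial copy numbers.
#' @param target_mask logical 3D array (`n_bins^3`) marking target voxels.
#' @param axes three node names defining the marginal.
#' @param bin_width,n_bins voxel geometry, must match `target_mask`.
#' @param seed integer seed.
#' @param max_events event budget per passage.
#' @return list(time, censored, events).
#' @export
first_passage <- function(network, init, target_mask, axes,
                          bin_width = 5, n_bins = 160, seed = 1,
                          max_events = 1e9) {
  nm <- node_names(network)
  stopifnot(length(axes) == 3, all(axes %in% nm),
            length(target_mask) == n_bins^3)
  n0 <- integer(length(nm)); names(n0) <- nm
  n0[names(init)] <- as.integer(init)
  mod <- pack_model(network)
  set.seed(as.integer(seed))
  res <- .ssa_run_cpp(mod, n0, integer(length(network$regulations)),
                      Inf, 0, 0,
                      match(axes, nm) - 1L, as.numeric(bin_width),
                      as.integer(n_bins), as.logical(target_mask),
                      as.numeric(max_events))
  list(time = res$fp_time, censored = is.na(res$fp_time), events = res$events)
}
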