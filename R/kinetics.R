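# Kinetics on the landscape: minimax saddle barriers between basins, mean
# first-passage times by direct simulation, the barrier/ln(time) correlation,
# and sequential-MFPT path-flux decomposition.

#' Minimax barriers between all basin pairs
#'
#' For each pair of basin minima the saddle is the minimax level: the lowest
#' `U` such that the two minima are connected through support voxels with
#' `U` at most that level (computed by a single ascending union-find sweep
#' over the 2d-connected support graph, equivalent to minimizing the maximal
#' `U` along any grid path). The barrier from A to B is
#' `U(saddle) - U_min(A)`, so the shared-saddle identity
#' `barrier(A->B) - barrier(B->A) = U_min(B) - U_min(A)` holds exactly.
#' Disconnected pairs get infinite barriers.
#'
#' @param grid a `landscape_grid`.
#' @param basins the `basin_set` from [find_basins()] (labeled or not).
#' @return data.frame with one row per ordered pair: `from`, `to` (labels if
#'   present, else basin ids), `barrier`, `U_saddle`, saddle voxel
#'   coordinates.
#' @export
barrier_matrix <- function(grid, basins) {
  d <- dim(grid$U)
  nb <- nrow(basins$summary)
  res <- .minimax_saddles_cpp(as.vector(grid$U), as.integer(d),
                              as.integer(basins$minima))
  sad_u <- res$U_saddle
  sad_vox <- res$voxel

  labels <- if (!is.null(basins$summary$label)) basins$summary$label
            else as.character(basins$summary$basin)
  Umin <- basins$summary$U_min
  pairs <- expand.grid(from = seq_len(nb), to = seq_len(nb))
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- data.frame(
    from = labels[pairs$from], to = labels[pairs$to],
    barrier = sad_u[cbind(pairs$from, pairs$to)] - Umin[pairs$from],
    U_saddle = sad_u[cbind(pairs$from, pairs$to)])
  vox <- sad_vox[cbind(pairs$from, pairs$to)]
  cc <- matrix(NA_real_, nrow(out), length(d))
  fin <- which(!is.na(vox))
  if (length(fin)) {
    aidx <- arrayInd(vox[fin], d)
    for (dd in seq_along(d)) cc[fin, dd] <- grid$centers[[dd]][aidx[, dd]]
  }
  colnames(cc) <- paste0("saddle_", grid$axes)
  cbind(out, as.data.frame(cc))
}

#' Barrier between two named basins
#' @param grid a `landscape_grid`.
#' @param basins a labeled `basin_set`.
#' @param from,to basin labels.
#' @return list(barrier, U_saddle, saddle coordinates).
#' @export
barrier_height <- function(grid, basins, from, to) {
  bm <- barrier_matrix(grid, basins)
  row <- bm[bm$from == from & bm$to == to, ]
  if (nrow(row) != 1) stop(sprintf("no barrier for %s -> %s", from, to))
  as.list(row)
}

#' Mean first-passage time between basins by direct simulation
#'
#' Trajectories start at the source basin minimum (all sites unbound) and run
#' until they first enter the target basin core: target-basin voxels with
#' `U <= U_min(target) + delta_core`. Passages exceeding `max_events` are
#' censored and excluded from the mean; estimates with more than 10%
#' censoring are flagged unreliable.
#'
#' @param network the `network_spec` that generated the landscape.
#' @param grid the `landscape_grid`.
#' @param basins a labeled `basin_set`.
#' @param from,to basin labels.
#' @param n_passages number of passages (>= 1; spec-grade estimates use >= 10).
#' @param seed master seed; one child seed per passage.
#' @param delta_core core entry tolerance in `U` units (default 1).
#' @param max_events event budget per passage.
#' @return An `mfpt_estimate`: mean, standard error, n_passages, times,
#'   censored count, reliability flag.
#' @export
mfpt <- function(network, grid, basins, from, to, n_passages = 10, seed = 1,
                 delta_core = 1, max_events = 5e8) {
  sm <- basins$summary
  ifrom <- match(from, sm$label); ito <- match(to, sm$label)
  if (is.na(ifrom) || is.na(ito)) stop("unknown basin label")
  d <- dim(grid$U)
  # target mask in engine voxel coordinates (n_bins grid, origin 0)
  n_bins_engine <- max(grid$origin + d) + 1L
  mask <- array(FALSE, rep(n_bins_engine, 3))
  lab <- basins$assignment
  core <- which(lab == ito & grid$U <= sm$U_min[ito] + delta_core)
  core_arr <- arrayInd(core, d)
  eng <- sweep(core_arr, 2, grid$origin, `+`)          # 1-based engine bins
  mask[eng] <- TRUE
  init <- round(unlist(sm[ifrom, grid$axes]))
  names(init) <- grid$axes
  seeds <- derive_seeds(seed, n_passages)
  times <- vapply(seq_len(n_passages), function(i) {
    fp <- first_passage(network, init, mask, grid$axes,
                        bin_width = grid$bin_width, n_bins = n_bins_engine,
                        seed = seeds[i], max_events = max_events)
    if (fp$censored) NA_real_ else fp$time
  }, 0)
  ok <- !is.na(times)
  censored <- sum(!ok)
  est <- structure(list(
    from = from, to = to,
    mean = if (any(ok)) mean(times[ok]) else NA_real_,
    se = if (sum(ok) > 1) sd(times[ok]) / sqrt(sum(ok)) else NA_real_,
    n_passages = sum(ok), censored = censored, times = times,
    reliable = censored <= 0.1 * n_passages && any(ok)),
    class = "mfpt_estimate")
  est
}

#' @export
print.mfpt_estimate <- function(x, ...) {
  cat(sprintf("MFPT %s -> %s: %.4g (se %.3g, n = %d, censored %d%s)\n",
              x$from, x$to, x$mean, x$se, x$n_passages, x$censored,
              if (!x$reliable) ", UNRELIABLE" else ""))
  invisible(x)
}

#' Correlation of barrier height with log transition time
#'
#' Pearson correlation of barrier heights against the natural logarithm of
#' the matched mean first-passage times.
#'
#' @param barriers numeric vector of barrier heights.
#' @param mfpts numeric vector of matching MFPTs (times, not logs).
#' @return Pearson r.
#' @export
barrier_time_correlation <- function(barriers, mfpts) {
  stopifnot(length(barriers) == length(mfpts), length(barriers) >= 3)
  if (var(barriers) == 0 || var(log(mfpts)) == 0)
    stop("zero variance: correlation undefined")
  cor(barriers, log(mfpts))
}

#' Path-flux decomposition of multi-step basin routes
#'
#' For each route the transition time is the sum of its step MFPTs, the path
#' rate is the reciprocal of that time, the flux is the stationary
#' probability of the shared source basin times the rate, and path
#' probabilities are fluxes normalized over the supplied routes.
#'
#' @param routes list of character vectors of basin labels (all sharing the
#'   same first and last element).
#' @param mfpts named list or data.frame of step MFPTs: names `"A->B"` or
#'   columns from/to/mean.
#' @param basin_probs named numeric vector of stationary basin probabilities
#'   (the `P_mass` column of a labeled basin summary).
#' @return A `path_result` data.frame: route, time, rate, flux, probability.
#' @export
path_flux <- function(routes, mfpts, basin_probs) {
  if (is.data.frame(mfpts)) {
    nmv <- paste0(mfpts$from, "->", mfpts$to)
    mfpts <- setNames(as.numeric(mfpts$mean), nmv)
  } else if (is.list(mfpts)) {
    mfpts <- unlist(mfpts)
  }
  src <- vapply(routes, `[`, "", 1)
  dst <- vapply(routes, function(r) r[length(r)], "")
  if (length(unique(src)) != 1 || length(unique(dst)) != 1)
    stop("routes must share source and destination")
  times <- vapply(routes, function(r) {
    steps <- paste0(r[-length(r)], "->", r[-1])
    miss <- setdiff(steps, names(mfpts))
    if (length(miss)) stop(sprintf("missing MFPT for step %s", miss[1]))
    sum(mfpts[steps])
  }, 0)
  rate <- 1 / times
  p_src <- basin_probs[[src[1]]]
  if (is.null(p_src) || is.na(p_src)) stop("missing stationary probability of source basin")
  flux <- p_src * rate
  out <- data.frame(
    route = vapply(routes, paste, "", collapse = " -> "),
    time = times, rate = rate, flux = flux,
    probability = flux / sum(flux))
  class(out) <- c("path_result", "data.frame")
  out
}
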