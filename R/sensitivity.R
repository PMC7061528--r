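# One-at-a-time sensitivity of barrier heights to regulation strength.
# "Strength" multiplies the binding rate h of a single regulation
# (equivalently divides its equilibrium constant Xeq = f/h); lambda-scaling
# is available behind the `scale_lambda` switch.

tracked_pairs_default <- function() {
  list(c("premalignant", "cancer"), c("cancer", "premalignant"),
       c("normal", "premalignant"), c("premalignant", "normal"),
       c("normal", "SC"), c("SC", "normal"))
}

#' Set the strength scale of one regulation
#' @param network a `network_spec`.
#' @param reg_id regulation id as produced by [regulation_id()].
#' @param scale dimensionless multiplier.
#' @param scale_lambda if TRUE, scale the synthesis fold `lambda` instead of
#'   the binding rate (alternative strength semantics; default FALSE).
#' @return The modified network.
#' @export
set_regulation_strength <- function(network, reg_id, scale, scale_lambda = FALSE) {
  ids <- vapply(network$regulations, regulation_id, "")
  i <- match(reg_id, ids)
  if (is.na(i)) stop(sprintf("unknown regulation \"%s\"", reg_id))
  if (scale_lambda) {
    network$regulations[[i]]$lambda <- network$regulations[[i]]$lambda * scale
  } else {
    network$regulations[[i]]$strength_scale <- scale
  }
  network
}

#' Landscape, labeled basins and barriers for one parameterization
#'
#' The repeated unit of the sensitivity module: simulate an ensemble
#' (dispersed marker-corner starts), estimate the landscape, find and label
#' basins, compute the minimax barrier matrix.
#'
#' @param network a `network_spec`.
#' @param t_max,n_runs,seed,burn_in simulation budget.
#' @param axes,bin_width,smooth_bw,merge_threshold,thresholds landscape and
#'   labeling settings (see [estimate_landscape()], [find_basins()],
#'   [label_basins()]).
#' @return list(grid, basins, barriers).
#' @export
run_barrier_pipeline <- function(network, t_max, n_runs, seed,
                                 axes = c("P53", "ZEB", "OCT4"),
                                 bin_width = 5, smooth_bw = 1,
                                 merge_threshold = 0.5, thresholds = NULL,
                                 burn_in = 0.1 * t_max) {
  inits <- if (all(axes %in% node_names(network)))
    dispersed_inits(network, axes = unique(axes)) else NULL
  ens <- ensemble_grn(network, n_runs = n_runs, t_max = t_max,
                      burn_in = burn_in, seed = seed, inits = inits,
                      record_every = 0, occupancy_axes = axes,
                      bin_width = bin_width)
  grid <- estimate_landscape(ens, axes = axes, bin_width = bin_width,
                             smooth_bw = smooth_bw)
  basins <- label_basins(find_basins(grid, merge_threshold), grid,
                         thresholds = thresholds)
  list(grid = grid, basins = basins,
       barriers = barrier_matrix(grid, basins))
}

lookup_barrier <- function(barriers, from, to) {
  row <- barriers[barriers$from == from & barriers$to == to, "barrier"]
  if (length(row) == 1 && is.finite(row)) row else NA_real_
}

#' Scan one regulation's strength and track barrier changes
#'
#' For each scale factor the regulation's `strength_scale` is set (all other
#' parameters at default), the landscape/basin/barrier pipeline is re-run on
#' a fixed seed ladder, and the tracked barriers are recorded together with
#' their deltas relative to scale 1.0. A basin missing at some scale yields
#' `NA` barriers with a reason, and the scan continues.
#'
#' @param network baseline `network_spec`.
#' @param reg_id regulation id, e.g. `"miR200-|ZEB"`.
#' @param scales multipliers within `[0.5, 2]`; must contain 1.
#' @param t_max,n_runs simulation budget per scan point.
#' @param seed seed ladder base; point `i` uses a deterministic child seed.
#' @param pairs list of `c(from, to)` barrier pairs to track (default: both
#'   directions of premalignant-cancer, normal-premalignant, normal-SC).
#' @param ... forwarded to the landscape pipeline (bin_width, smooth_bw,
#'   merge_threshold, thresholds, burn_in).
#' @return A `sensitivity_scan`: long data.frame (regulation, scale, from,
#'   to, barrier, delta) plus notes on missing basins.
#' @export
scan_regulation <- function(network, reg_id, scales = c(0.8, 1, 1.5),
                            t_max = 2000, n_runs = 4, seed = 1,
                            pairs = tracked_pairs_default(), ...) {
  stopifnot(all(scales >= 0.5 & scales <= 2), any(scales == 1))
  seeds <- derive_seeds(seed, length(scales))
  notes <- character()
  rows <- list()
  for (i in seq_along(scales)) {
    sc <- scales[i]
    net_i <- set_regulation_strength(network, reg_id, sc)
    res <- run_barrier_pipeline(net_i, t_max = t_max, n_runs = n_runs,
                                seed = seeds[i], ...)
    labs <- res$basins$summary$label
    for (pr in pairs) {
      b <- if (all(pr %in% labs)) lookup_barrier(res$barriers, pr[1], pr[2])
           else NA_real_
      if (is.na(b) && !all(pr %in% labs))
        notes <- c(notes, sprintf("scale %g: basin %s missing", sc,
                                  paste(setdiff(pr, labs), collapse = ",")))
      rows[[length(rows) + 1]] <- data.frame(
        regulation = reg_id, scale = sc, from = pr[1], to = pr[2], barrier = b)
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$scale == 1, ]
  key <- paste(out$from, out$to)
  bkey <- paste(base$from, base$to)
  out$delta <- out$barrier - base$barrier[match(key, bkey)]
  structure(list(table = out, regulation = reg_id, scales = scales,
                 notes = unique(notes)),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat(sprintf("sensitivity_scan of %s over scales {%s}\n", x$regulation,
              paste(x$scales, collapse = ", ")))
  print(x$table, row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Rank regulations by barrier sensitivity
#'
#' Aggregates each scan by the maximum absolute barrier delta across tracked
#' pairs and non-unit scales; ties broken lexicographically by regulation id.
#'
#' @param scans list of `sensitivity_scan` objects sharing scales and pairs.
#' @return data.frame (regulation, max_abs_delta) ordered most-sensitive first.
#' @export
rank_regulations <- function(scans) {
  agg <- vapply(scans, function(s) {
    tb <- s$table[s$table$scale != 1, ]
    m <- suppressWarnings(max(abs(tb$delta), na.rm = TRUE))
    if (!is.finite(m)) 0 else m
  }, 0)
  ids <- vapply(scans, `[[`, "", "regulation")
  o <- order(-agg, ids)
  data.frame(regulation = ids[o], max_abs_delta = agg[o])
}

#' Saturation probe of P53 self-activation strength
#'
#' Tracks the normal/premalignant barrier deltas across a scale ladder and
#' flags saturation where successive deltas fall below a noise threshold.
#'
#' @param network baseline network (must contain `P53->P53`).
#' @param scales scale ladder (default `c(0.9, 1, 1.1, 1.2, 1.3)`).
#' @param noise_threshold smallest delta change considered real (default 2x
#'   the pooled baseline standard error if supplied, else 0.2 U).
#' @param ... forwarded to [scan_regulation()].
#' @return data.frame of deltas per scale with a `saturated` flag, or the
#'   table from a pre-computed scan passed via `scan`.
#' @param scan optional pre-computed `sensitivity_scan` of `P53->P53` to
#'   analyse instead of re-simulating.
#' @export
p53_nonmonotonicity_probe <- function(network = NULL,
                                      scales = c(0.9, 1, 1.1, 1.2, 1.3),
                                      noise_threshold = 0.2, scan = NULL, ...) {
  if (is.null(scan)) {
    if (!any(scales == 1)) scales <- sort(c(1, scales))
    scan <- scan_regulation(network, "P53->P53", scales = scales,
                            pairs = list(c("normal", "premalignant"),
                                         c("premalignant", "normal")), ...)
  }
  tb <- scan$table
  tb <- tb[order(tb$from, tb$to, tb$scale), ]
  out <- do.call(rbind, lapply(split(tb, paste(tb$from, tb$to)), function(g) {
    g$saturated <- c(FALSE, abs(diff(g$delta)) < noise_threshold)
    g
  }))
  rownames(out) <- NULL
  out
}
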