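# Landscape quantification: steady-state probability P over a 3-species
# marginal, potential U = -ln P, basin detection by steepest-descent
# watershed with persistence merging, and labeling of the seven cell states.

#' Estimate the potential landscape from an ensemble
#'
#' Pools time-weighted occupancy across ensemble members (post burn-in),
#' normalizes to a probability `P` over copy-number voxels, optionally
#' smooths with a separable Gaussian kernel, and sets `U = -ln P` on the
#' support. Trajectories simulated with `occupancy_axes` carry an exact
#' dwell-time histogram which is used directly; otherwise thinned records
#' are binned with equal weights.
#'
#' @param ensemble a `trajectory_ensemble` or list of `trajectory` objects.
#' @param axes three node names (default `c("P53","ZEB","OCT4")`).
#' @param bin_width copy-number bin width (default 5).
#' @param smooth_bw Gaussian kernel bandwidth in bins (0 disables smoothing).
#' @return A `landscape_grid`: arrays `P` (sums to 1) and `U` (finite exactly
#'   where `P > 0`), voxel `centers` per axis, `axes`, `bin_width`,
#'   `total_weight` (pooled simulated time or record count).
#' @export
estimate_landscape <- function(ensemble, axes = c("P53", "ZEB", "OCT4"),
                               bin_width = 5, smooth_bw = 1) {
  if (inherits(ensemble, "trajectory")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1, length(axes) == 3)

  use_occ <- all(vapply(ensemble, function(tr) {
    !is.null(tr$occupancy) &&
      identical(attr(tr$occupancy, "axes"), axes) &&
      isTRUE(all.equal(attr(tr$occupancy, "bin_width"), bin_width))
  }, TRUE))

  if (use_occ) {
    H <- Reduce(`+`, lapply(ensemble, function(tr) {
      a <- tr$occupancy; attributes(a) <- list(dim = dim(a)); a
    }))
  } else {
    recs <- lapply(ensemble, function(tr) {
      if (is.null(tr$records)) stop("trajectory has neither occupancy histogram nor records")
      r <- tr$records[tr$records$time >= tr$burn_in, axes, drop = FALSE]
      if (nrow(r) == 0) stop("no post-burn-in records in trajectory")
      r
    })
    X <- do.call(rbind, recs)
    nb <- max(2L, ceiling((max(X) + 1) / bin_width))
    H <- array(0, dim = rep(nb, 3))
    idx <- 1 + pmin(floor(as.matrix(X) / bin_width), nb - 1L)
    lin <- idx[, 1] + nb * (idx[, 2] - 1L) + nb * nb * (idx[, 3] - 1L)
    tab <- tabulate(lin, nbins = nb^3)
    H[] <- tab
  }
  total <- sum(H)
  if (total <= 0) stop("empty landscape: no post-burn-in occupancy")

  # crop to the populated bounding box plus kernel radius
  r <- if (smooth_bw > 0) ceiling(4 * smooth_bw) else 0L
  nz <- which(H > 0, arr.ind = TRUE)
  lo <- pmax(apply(nz, 2, min) - r, 1L)
  hi <- pmin(apply(nz, 2, max) + r, dim(H))
  H <- H[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  P <- H / sum(H)
  if (smooth_bw > 0) P <- gauss_smooth(P, smooth_bw)
  P <- P / sum(P)
  U <- -log(P)
  U[!is.finite(U)] <- NA_real_

  centers <- lapply(1:3, function(d)
    ((lo[d] - 1) + seq_len(dim(P)[d]) - 0.5) * bin_width)
  names(centers) <- axes
  structure(list(P = P, U = U, axes = axes, bin_width = bin_width,
                 origin = lo - 1L, centers = centers,
                 smooth_bw = smooth_bw, total_weight = total),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid over (%s): %s voxels (bin %g), support %d, U range [%.2f, %.2f]\n",
              paste(x$axes, collapse = ", "), paste(dim(x$P), collapse = "x"),
              x$bin_width, sum(is.finite(x$U)),
              min(x$U, na.rm = TRUE), max(x$U, na.rm = TRUE)))
  invisible(x)
}

# Separable Gaussian smoothing of a 2D/3D array (zero-padded edges).
gauss_smooth <- function(P, bw) {
  r <- ceiling(4 * bw)
  k <- stats::dnorm(-r:r, sd = bw)
  k <- k / sum(k)
  d <- dim(P)
  for (dd in seq_along(d)) {
    out <- array(0, d)
    for (o in -r:r) {
      w <- k[o + r + 1]
      n <- d[dd]
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      idx_to <- which(ok); idx_from <- src[ok]
      if (dd == 1) out[idx_to, , ] <- out[idx_to, , , drop = FALSE] + w * P[idx_from, , , drop = FALSE]
      else if (dd == 2) out[, idx_to, ] <- out[, idx_to, , drop = FALSE] + w * P[, idx_from, , drop = FALSE]
      else out[, , idx_to] <- out[, , idx_to, drop = FALSE] + w * P[, , idx_from, drop = FALSE]
    }
    P <- out
  }
  P
}

# linear indices of the 2n axis neighbors of linear voxel i in an array of dims d
neighbor_offsets <- function(d) {
  mult <- cumprod(c(1, d[-length(d)]))
  c(mult, -mult)
}

# arr.ind for linear indices
lin_to_arr <- function(i, d) arrayInd(i, d)

#' Detect attractor basins on a landscape
#'
#' Orders support voxels by increasing `U` and floods: a voxel with no
#' already-labeled lower (or equal-`U`) neighbor opens a new basin at a local
#' minimum; otherwise it joins the catchment of its lowest labeled neighbor
#' (steepest-descent watershed, 2d-connectivity). Minima whose depth below
#' their lowest saddle is less than `merge_threshold` are merged into the
#' neighbor across that saddle (persistence merging), absorbing sampling
#' noise.
#'
#' @param grid a `landscape_grid` (3D) or a projected 2D grid.
#' @param merge_threshold minimum basin depth in `U` units (default 0.5).
#' @return A `basin_set`: `summary` data.frame (basin id, minimum
#'   coordinates, `U_min`, probability mass, voxel count), `assignment`
#'   integer array (NA off support), and the `grid` geometry.
#' @export
find_basins <- function(grid, merge_threshold = 0.5) {
  U <- grid$U
  d <- dim(U)
  Uv <- as.vector(U)
  ws <- .watershed_cpp(Uv, as.integer(d))
  labv <- ws$labels
  n_min <- ws$minima
  lab <- array(labv, d)

  # persistence merging of shallow minima
  repeat {
    nb <- length(n_min)
    if (nb <= 1) break
    sad <- basin_saddles(Uv, labv, d, nb)
    Umin <- Uv[n_min]
    depth <- apply(sad, 1, min, na.rm = TRUE) - Umin
    depth[!is.finite(depth)] <- Inf
    cand <- which(depth < merge_threshold)
    if (!length(cand)) break
    b <- cand[which.max(Umin[cand])]        # merge shallowest-from-top first
    into <- which.min(sad[b, ])
    labv[labv == b] <- into
    keep <- setdiff(seq_len(nb), b)
    relab <- match(labv, keep)
    labv <- relab
    n_min <- n_min[keep]
  }
  lab[] <- labv

  Umin <- Uv[n_min]
  o <- order(Umin)
  relab <- match(labv, o)
  labv <- relab; lab[] <- labv
  n_min <- n_min[o]; Umin <- Umin[o]

  coords <- arrayInd(n_min, d)
  cc <- sapply(seq_along(d), function(dd) grid$centers[[dd]][coords[, dd]])
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = length(n_min))
  colnames(cc) <- grid$axes
  Pv <- as.vector(grid$P)
  mass <- vapply(seq_along(n_min), function(b) sum(Pv[which(labv == b)]), 0)
  summary <- data.frame(basin = seq_along(n_min), U_min = Umin,
                        P_mass = mass,
                        n_voxels = tabulate(labv[!is.na(labv)], length(n_min)))
  summary <- cbind(summary, as.data.frame(cc))
  structure(list(summary = summary, assignment = lab, minima = n_min,
                 grid = grid[c("axes", "bin_width", "origin", "centers")],
                 merge_threshold = merge_threshold),
            class = "basin_set")
}

# lowest boundary saddle between each ordered basin pair:
# sad[a, b] = min over adjacent voxel pairs (i in a, j in b) of max(U_i, U_j)
basin_saddles <- function(Uv, labv, d, nb) {
  sad <- matrix(Inf, nb, nb)
  L <- array(seq_len(prod(d)), d)
  slice <- function(dd, head) {
    idx <- lapply(d, seq_len)
    idx[[dd]] <- if (head) seq_len(d[dd] - 1L) else 1L + seq_len(d[dd] - 1L)
    do.call(`[`, c(list(L), idx))
  }
  for (dd in seq_along(d)) {
    if (d[dd] < 2) next
    i <- as.vector(slice(dd, TRUE)); j <- as.vector(slice(dd, FALSE))
    la <- labv[i]; lb <- labv[j]
    ok <- !is.na(la) & !is.na(lb) & la != lb
    if (!any(ok)) next
    u <- pmax(Uv[i[ok]], Uv[j[ok]])
    a <- la[ok]; b <- lb[ok]
    key <- paste(pmin(a, b), pmax(a, b))
    agg <- tapply(u, key, min)
    for (kk in seq_along(agg)) {
      ab <- as.integer(strsplit(names(agg)[kk], " ")[[1]])
      if (agg[kk] < sad[ab[1], ab[2]]) {
        sad[ab[1], ab[2]] <- agg[kk]; sad[ab[2], ab[1]] <- agg[kk]
      }
    }
  }
  diag(sad) <- NA
  sad
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("basin_set: %d basins (merge threshold %g)\n",
              nrow(x$summary), x$merge_threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' The seven cell-state signatures
#'
#' Qualitative expression patterns of the seven attractors over
#' (P53, OCT4, ZEB): e.g. normal = P53 high, OCT4 low, ZEB low; lesion = all
#' low; CSC = all intermediate.
#'
#' @return data.frame with columns label, P53, OCT4, ZEB (levels
#'   "low"/"intermediate"/"high").
#' @export
state_signatures <- function() {
  data.frame(
    label = c("normal", "premalignant", "cancer", "SC", "CSC",
              "lesion", "hyperplasia"),
    P53  = c("high", "intermediate", "low", "high", "intermediate", "low", "low"),
    OCT4 = c("low", "low", "low", "high", "intermediate", "low", "high"),
    ZEB  = c("low", "intermediate", "high", "low", "intermediate", "low", "low"),
    stringsAsFactors = FALSE
  )
}

#' Label basins with the seven cell states
#'
#' Each basin minimum is discretized to low/intermediate/high per axis and
#' matched against [state_signatures()]. Unmatched minima become
#' `"unassigned"`. If two basins map to the same signature the deeper
#' (lower `U_min`) keeps the label.
#'
#' @param basins a `basin_set` over axes including P53, OCT4 and ZEB.
#' @param grid the `landscape_grid` the basins came from.
#' @param thresholds named list of per-axis cut points `c(t1, t2)` in copy
#'   numbers; default: tertiles of each axis' support range.
#' @return The `basin_set` with a `label` column added to its summary.
#' @export
label_basins <- function(basins, grid, thresholds = NULL) {
  axes <- grid$axes
  if (is.null(thresholds)) {
    sup <- which(is.finite(grid$U), arr.ind = TRUE)
    thresholds <- lapply(seq_along(axes), function(dd) {
      rng <- range(grid$centers[[dd]][sup[, dd]])
      rng[1] + diff(rng) * c(1, 2) / 3
    })
    names(thresholds) <- axes
  }
  level_of <- function(x, cuts) {
    if (x < cuts[1]) "low" else if (x <= cuts[2]) "intermediate" else "high"
  }
  sig <- state_signatures()
  sm <- basins$summary
  lv <- sapply(c("P53", "OCT4", "ZEB"), function(ax)
    vapply(sm[[ax]], level_of, "", cuts = thresholds[[ax]]))
  if (is.null(dim(lv))) lv <- matrix(lv, nrow = nrow(sm),
                                     dimnames = list(NULL, c("P53", "OCT4", "ZEB")))
  lab <- rep("unassigned", nrow(sm))
  for (i in seq_len(nrow(sm))) {
    hit <- which(sig$P53 == lv[i, "P53"] & sig$OCT4 == lv[i, "OCT4"] &
                   sig$ZEB == lv[i, "ZEB"])
    if (length(hit) == 1) lab[i] <- sig$label[hit]
  }
  # unique labels: deeper basin wins ties
  for (l in unique(lab[lab != "unassigned"])) {
    dup <- which(lab == l)
    if (length(dup) > 1) {
      keep <- dup[which.min(sm$U_min[dup])]
      lab[setdiff(dup, keep)] <- "unassigned"
    }
  }
  basins$summary$label <- lab
  basins$summary$P53_level <- lv[, "P53"]
  basins$summary$OCT4_level <- lv[, "OCT4"]
  basins$summary$ZEB_level <- lv[, "ZEB"]
  basins$thresholds <- thresholds
  basins
}

#' Project a landscape onto an axis pair
#'
#' Marginalizes `P` over the dropped axis and recomputes `U = -ln P`.
#'
#' @param grid a 3D `landscape_grid`.
#' @param axes two of the grid's axis names, in the desired order.
#' @return A 2D `landscape_grid`.
#' @export
project_landscape <- function(grid, axes) {
  stopifnot(length(axes) == 2, all(axes %in% grid$axes))
  keep <- match(axes, grid$axes)
  P2 <- apply(grid$P, keep, sum)
  U2 <- -log(P2); U2[!is.finite(U2)] <- NA_real_
  structure(list(P = P2, U = U2, axes = axes, bin_width = grid$bin_width,
                 origin = grid$origin[keep], centers = grid$centers[axes],
                 smooth_bw = grid$smooth_bw, total_weight = grid$total_weight),
            class = "landscape_grid")
}

#' Count distinguishable modes of a (projected) landscape
#'
#' Runs the same watershed + persistence merging as [find_basins()] and
#' returns the number of basins whose depth exceeds the merge threshold.
#'
#' @param grid a `landscape_grid` (2D or 3D).
#' @param merge_threshold persistence threshold in `U` units.
#' @return Integer mode count.
#' @export
count_modes <- function(grid, merge_threshold = 0.5) {
  nrow(find_basins(grid, merge_threshold)$summary)
}

#' Build a landscape grid from an explicit probability array
#'
#' Mainly for tests and synthetic examples: wraps a non-negative array as a
#' `landscape_grid` (normalized, `U = -ln P`).
#'
#' @param P non-negative 2D/3D array.
#' @param axes axis names (default x1..xd).
#' @param bin_width voxel width (default 1).
#' @return A `landscape_grid`.
#' @export
landscape_from_probability <- function(P, axes = NULL, bin_width = 1) {
  d <- dim(P)
  if (is.null(axes)) axes <- paste0("x", seq_along(d))
  stopifnot(length(axes) == length(d), all(P >= 0), sum(P) > 0)
  P <- P / sum(P)
  U <- -log(P); U[!is.finite(U)] <- NA_real_
  centers <- lapply(d, function(n) (seq_len(n) - 0.5) * bin_width)
  names(centers) <- axes
  structure(list(P = P, U = U, axes = axes, bin_width = bin_width,
                 origin = rep(0L, length(d)), centers = centers,
                 smooth_bw = 0, total_weight = 1),
            class = "landscape_grid")
}
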