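# Direct (truncated) chemical master equation solution for test-scale
# systems. Used as an independent oracle against the SSA: the state space is
# enumerated exactly (copy numbers x binding-site flags), the generator is
# assembled sparsely, and the stationary vector solved by linear algebra.

#' Enumerate the truncated state space of a small network
#'
#' States are all combinations of free copy numbers `0..truncation` per
#' species and bound/unbound flags per regulation. Only feasible for systems
#' with about <= 1e5 states.
#'
#' @param network a `network_spec`.
#' @param truncation max free copy number per species (scalar or per-species).
#' @return data.frame of states; copy-number columns named after nodes,
#'   flag columns `site1..siteR`.
#' @export
enumerate_states <- function(network, truncation) {
  nm <- node_names(network)
  R <- length(network$regulations)
  trunc <- rep_len(truncation, length(nm))
  grids <- c(lapply(trunc, function(tr) 0:tr),
             rep(list(0:1), R))
  names(grids) <- c(nm, if (R) paste0("site", seq_len(R)))
  st <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  if (nrow(st) > 2e5)
    stop("truncated state space too large for the reference solver")
  st
}

#' Sparse generator of the truncated master equation
#'
#' Entry `Q[i, j]` is the rate from state `i` to state `j`; rows sum to zero
#' (transitions leaving the truncation box are dropped, which is the usual
#' reflecting truncation).
#'
#' @inheritParams enumerate_states
#' @return list(states, Q) with `Q` a sparse `dgCMatrix`.
#' @export
cme_generator <- function(network, truncation) {
  st <- enumerate_states(network, truncation)
  nm <- node_names(network)
  regs <- network$regulations
  S <- length(nm); R <- length(regs)
  N <- nrow(st)
  trunc <- rep_len(truncation, S)

  # index arithmetic: mixed-radix over (copy numbers, flags)
  radix <- c(trunc + 1, rep(2L, R))
  mult <- cumprod(c(1, radix[-length(radix)]))
  idx_of <- function(mat) as.integer(as.matrix(mat) %*% mult) + 1L

  cols <- as.matrix(st)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    keep <- rate > 0
    ii <<- c(ii, from[keep]); jj <<- c(jj, to[keep]); xx <<- c(xx, rate[keep])
  }
  from_all <- seq_len(N)

  for (j in seq_len(S)) {
    nj <- cols[, j]
    occ_sites <- which(vapply(regs, function(r) r$target == nm[j], TRUE))
    g <- rep(network$nodes[[j]]$g0, N)
    for (s in occ_sites) g <- g * ifelse(cols[, S + s] == 1, regs[[s]]$lambda, 1)
    # synthesis (reflecting at the truncation boundary)
    ok <- nj < trunc[j]
    to <- from_all + mult[j]
    add(from_all[ok], to[ok], g[ok])
    # degradation of free copies
    ok <- nj > 0
    add(from_all[ok], (from_all - mult[j])[ok], (network$nodes[[j]]$k * nj)[ok])
  }
  for (s in seq_len(R)) {
    r <- regs[[s]]
    js <- match(r$source, nm)
    nsrc <- cols[, js]
    flag <- cols[, S + s]
    # binding: flag 0 -> 1, source loses m copies
    ok <- flag == 0 & nsrc >= r$m
    rate <- binding_propensity(r, nsrc)
    to <- from_all + mult[S + s] - r$m * mult[js]
    add(from_all[ok], to[ok], rate[ok])
    # unbinding: flag 1 -> 0, source regains m copies (reflecting cap)
    ok <- flag == 1 & (nsrc + r$m) <= trunc[js]
    to <- from_all - mult[S + s] + r$m * mult[js]
    add(from_all[ok], to[ok], rep(r$f, N)[ok])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  list(states = st, Q = Q)
}

#' Stationary distribution of the truncated master equation
#'
#' Solves `p' Q = 0`, `sum(p) = 1` by replacing one balance equation with the
#' normalization row. Warns when the truncation boundary carries more than
#' `boundary_tol` probability mass.
#'
#' @inheritParams enumerate_states
#' @param boundary_tol tolerated probability mass on the truncation boundary.
#' @return list(states, p, boundary_mass).
#' @export
solve_cme_reference <- function(network, truncation, boundary_tol = 1e-6) {
  gen <- cme_generator(network, truncation)
  N <- nrow(gen$states)
  A <- Matrix::t(gen$Q)
  A[N, ] <- 1
  b <- c(rep(0, N - 1), 1)
  p <- as.numeric(Matrix::solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  nm <- node_names(network)
  trunc <- rep_len(truncation, length(nm))
  on_boundary <- Reduce(`|`, lapply(seq_along(nm), function(j)
    gen$states[[nm[j]]] == trunc[j]))
  bm <- sum(p[on_boundary])
  if (bm > boundary_tol)
    warning(sprintf("truncation boundary carries %.2g probability mass; increase truncation", bm))
  list(states = gen$states, p = p, boundary_mass = bm)
}

#' Marginal stationary law of one species from the reference solution
#' @param ref result of [solve_cme_reference()].
#' @param node node name.
#' @return data.frame(n, p).
#' @export
cme_marginal <- function(ref, node) {
  tab <- tapply(ref$p, ref$states[[node]], sum)
  data.frame(n = as.integer(names(tab)), p = as.numeric(tab))
}
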