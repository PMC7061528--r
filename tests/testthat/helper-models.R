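# Tiny networks and synthetic grids shared across tests.

# one unregulated gene: birth-death with rates g0, k
unregulated_gene <- function(g0 = 50, k = 1) {
  network_spec(list(gene_node("A", g0 = g0, k = k)), list(),
               params = parameter_set(g0 = g0, k = k))
}

# one gene repressed by its own product through a monomer site
self_repressor <- function(g0 = 50, k = 1, h = 2, omega = 10, lambda_r = 0.5) {
  p <- parameter_set(g0 = g0, k = k, h_r = h, omega = omega,
                     lambda_r = lambda_r)
  network_spec(list(gene_node("A", g0 = g0, k = k)),
               list(regulation("A", "A", "repression", m = 1)),
               params = p)
}

# two genes, B repressed by A (monomer site)
two_gene_repression <- function(g0 = 20, k = 1, omega = 10) {
  p <- parameter_set(g0 = g0, k = k, omega = omega)
  network_spec(list(gene_node("A", g0 = g0, k = k),
                    gene_node("B", g0 = g0, k = k)),
               list(regulation("A", "B", "repression", m = 1)),
               params = p)
}

# analytic 3D probability: mixture of separable Gaussians at given centers
gaussian_mixture_grid <- function(centers, sd = 2, n = 24, weights = NULL,
                                  bin_width = 1) {
  if (is.null(weights)) weights <- rep(1 / nrow(centers), nrow(centers))
  ax <- (seq_len(n) - 0.5) * bin_width
  P <- array(0, dim = rep(n, 3))
  for (s in seq_len(nrow(centers))) {
    px <- stats::dnorm(ax, centers[s, 1], sd)
    py <- stats::dnorm(ax, centers[s, 2], sd)
    pz <- stats::dnorm(ax, centers[s, 3], sd)
    P <- P + weights[s] * outer(outer(px, py), pz)
  }
  landscape_from_probability(P, bin_width = bin_width)
}

# exhaustive minimax saddle between two voxels on a small grid:
# Floyd-Warshall widest-path with edge weight max(U_i, U_j)
minimax_oracle <- function(U) {
  d <- dim(U)
  nvox <- prod(U = prod(d))
  fin <- is.finite(U)
  D <- matrix(Inf, prod(d), prod(d))
  idx <- array(seq_len(prod(d)), d)
  for (i in which(fin)) {
    D[i, i] <- U[i]
    ai <- arrayInd(i, d)
    for (dd in seq_along(d)) for (step in c(-1L, 1L)) {
      aj <- ai
      aj[dd] <- aj[dd] + step
      if (aj[dd] < 1L || aj[dd] > d[dd]) next
      j <- idx[matrix(aj, 1)]
      if (fin[j]) D[i, j] <- max(U[i], U[j])
    }
  }
  for (k in which(fin)) {
    Dk <- outer(D[, k], D[k, ], pmax)
    D <- pmin(D, Dk)
  }
  D
}

# MFPT oracle on an explicit CTMC generator: solve (Q_AA) t = -1 over
# non-target states; t[start] is the MFPT to the target set.
mfpt_ctmc_oracle <- function(Q, start, targets) {
  keep <- setdiff(seq_len(nrow(Q)), targets)
  t_keep <- solve(as.matrix(Q[keep, keep, drop = FALSE]),
                  rep(-1, length(keep)))
  tt <- numeric(nrow(Q))
  tt[keep] <- t_keep
  tt[start]
}
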