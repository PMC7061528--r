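# Landscape estimation, basin detection, labeling, projection.

test_that("uniform occupancy gives constant U = ln(support)", {
  P <- array(0, c(4, 4, 4))
  P[1:2, 1:2, 1:2] <- 1          # 8 voxels of equal weight
  g <- landscape_from_probability(P)
  expect_equal(sum(g$P), 1)
  u <- g$U[is.finite(g$U)]
  expect_length(u, 8)
  expect_true(all(abs(u - log(8)) < 1e-12))
})

test_that("U differences equal log probability ratios", {
  P <- array(0, c(3, 3, 3))
  P[1, 1, 1] <- 1
  P[2, 1, 1] <- exp(-2)
  g <- landscape_from_probability(P)
  expect_equal(g$U[2, 1, 1] - g$U[1, 1, 1], 2, tolerance = 1e-12)
  # argmin of U is argmax of P
  expect_equal(which.min(g$U), which.max(g$P))
})

test_that("estimate_landscape normalizes and uses records or occupancy", {
  net <- unregulated_gene()
  tr <- simulate_grn(net, t_max = 60, seed = 1, record_every = 0.2,
                     burn_in = 5)
  # fake three axes by reusing the single species (records path)
  ens <- list(tr)
  class(ens) <- c("trajectory_ensemble", "list")
  g <- estimate_landscape(ens, axes = c("A", "A", "A"), bin_width = 5,
                          smooth_bw = 0)
  expect_equal(sum(g$P), 1, tolerance = 1e-9)
  expect_true(all(is.finite(g$U[g$P > 0])))
  expect_true(all(is.na(g$U[g$P == 0])))
  # exact occupancy path
  tr2 <- simulate_grn(net, t_max = 60, seed = 1, record_every = 0,
                      burn_in = 5, occupancy_axes = c("A", "A", "A"))
  g2 <- estimate_landscape(list(tr2), axes = c("A", "A", "A"), bin_width = 5,
                           smooth_bw = 0)
  expect_equal(sum(g2$P), 1, tolerance = 1e-9)
})

test_that("smoothing preserves interior mass and the pipeline renormalizes", {
  P <- array(0, c(20, 20, 20))
  P[8:12, 8:12, 8:12] <- 1    # mass far from edges: kernel loses nothing
  g <- landscape_from_probability(P)
  sm <- gauss_smooth(g$P, bw = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_true(all(sm >= 0))
})

test_that("single well yields one basin; two wells two basins at the centers", {
  g1 <- gaussian_mixture_grid(matrix(c(12, 12, 12), 1), sd = 2.5)
  b1 <- find_basins(g1)
  expect_equal(nrow(b1$summary), 1)

  centers <- rbind(c(7, 7, 7), c(18, 18, 18))
  g2 <- gaussian_mixture_grid(centers, sd = 1.6)
  b2 <- find_basins(g2)
  expect_equal(nrow(b2$summary), 2)
  found <- as.matrix(b2$summary[, g2$axes])
  d <- as.matrix(dist(rbind(found, centers - 0.5)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 2)   # minima at the Gaussian centers
})

test_that("watershed partitions the support exactly once", {
  centers <- rbind(c(7, 7, 7), c(18, 18, 18), c(7, 18, 7))
  g <- gaussian_mixture_grid(centers, sd = 1.8)
  b <- find_basins(g)
  sup <- is.finite(g$U)
  expect_true(all(!is.na(b$assignment[sup])))
  expect_true(all(is.na(b$assignment[!sup])))
  expect_equal(sum(b$summary$n_voxels), sum(sup))
  expect_equal(sum(b$summary$P_mass), 1, tolerance = 1e-9)
})

test_that("shallow minima merge under the persistence threshold", {
  # two wells of unequal depth: the shallow one survives a tiny threshold
  # and merges under a large one
  centers <- rbind(c(9, 9, 9), c(16, 9, 9))
  g <- gaussian_mixture_grid(centers, sd = 1.5, weights = c(0.8, 0.2))
  n_small <- nrow(find_basins(g, merge_threshold = 1e-9)$summary)
  n_big <- nrow(find_basins(g, merge_threshold = 6)$summary)
  expect_gte(n_small, 2)
  expect_equal(n_big, 1)
})

test_that("labeling maps signature patterns and resolves conflicts", {
  sig <- state_signatures()
  expect_equal(nrow(sig), 7)
  expect_equal(anyDuplicated(sig[, c("P53", "OCT4", "ZEB")]), 0)

  # synthetic three-well landscape on (P53, ZEB, OCT4) axes
  centers <- rbind(c(21, 3, 3),    # P53 high, ZEB low, OCT4 low -> normal
                   c(3, 21, 3),    # cancer
                   c(3, 3, 3))     # lesion
  g <- gaussian_mixture_grid(centers, sd = 1.5)
  g$axes <- c("P53", "ZEB", "OCT4")
  names(g$centers) <- g$axes
  b <- label_basins(find_basins(g), g,
                    thresholds = list(P53 = c(8, 16), ZEB = c(8, 16),
                                      OCT4 = c(8, 16)))
  labs <- b$summary$label
  expect_setequal(labs, c("normal", "cancer", "lesion"))
  # CSC: all intermediate
  g2 <- gaussian_mixture_grid(matrix(c(12, 12, 12), 1), sd = 1.5)
  g2$axes <- c("P53", "ZEB", "OCT4"); names(g2$centers) <- g2$axes
  b2 <- label_basins(find_basins(g2), g2,
                     thresholds = list(P53 = c(8, 16), ZEB = c(8, 16),
                                       OCT4 = c(8, 16)))
  expect_equal(b2$summary$label, "CSC")
})

test_that("labeling is invariant to basin order and labels stay unique", {
  centers <- rbind(c(21, 3, 3), c(3, 21, 3), c(3, 3, 21), c(3, 3, 3))
  g <- gaussian_mixture_grid(centers, sd = 1.5)
  g$axes <- c("P53", "ZEB", "OCT4"); names(g$centers) <- g$axes
  thr <- list(P53 = c(8, 16), ZEB = c(8, 16), OCT4 = c(8, 16))
  b <- label_basins(find_basins(g), g, thresholds = thr)
  labs <- b$summary$label[b$summary$label != "unassigned"]
  expect_equal(anyDuplicated(labs), 0)
  expect_setequal(b$summary$label, c("normal", "cancer", "hyperplasia", "lesion"))
})

test_that("projection marginalizes correctly and conserves mass", {
  centers <- rbind(c(7, 7, 7), c(18, 18, 18))
  g <- gaussian_mixture_grid(centers, sd = 1.6)
  p2 <- project_landscape(g, g$axes[c(1, 2)])
  expect_equal(sum(p2$P), 1, tolerance = 1e-9)
  expect_equal(dim(p2$P), dim(g$P)[1:2])
  expect_equal(p2$P, apply(g$P, c(1, 2), sum), tolerance = 1e-12)
  # the two modes survive the projection (they are diagonal)
  expect_equal(count_modes(p2, merge_threshold = 0.5), 2)
  # projecting a pair of wells that coincide along the kept axes merges them
  centers2 <- rbind(c(7, 7, 4), c(7, 7, 20))
  g2 <- gaussian_mixture_grid(centers2, sd = 1.6)
  p22 <- project_landscape(g2, g2$axes[c(1, 2)])
  expect_equal(count_modes(p22, merge_threshold = 0.5), 1)
})

test_that("basin count is stable under halving the bin width", {
  # analytic two-well probability sampled at two resolutions
  mk <- function(n, bw) {
    ax <- (seq_len(n) - 0.5) * bw
    P <- array(0, c(n, n, n))
    for (s in 1:2) {
      cc <- list(c(8, 8, 8), c(17, 17, 17))[[s]]
      P <- P + outer(outer(dnorm(ax, cc[1], 2), dnorm(ax, cc[2], 2)),
                     dnorm(ax, cc[3], 2))
    }
    landscape_from_probability(P, bin_width = bw)
  }
  expect_equal(nrow(find_basins(mk(25, 1))$summary),
               nrow(find_basins(mk(50, 0.5))$summary))
})
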