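# Barriers (minimax saddles), MFPT, correlation, path flux.

test_that("1D-like barrier reads off the single path", {
  # U along a line: 0, 3, 1 -> barrier A->B = 3, B->A = 2
  U <- array(NA_real_, c(3, 1, 1))
  U[, 1, 1] <- c(0, 3, 1)
  P <- exp(-U); P[is.na(P)] <- 0
  g <- landscape_from_probability(P)
  b <- find_basins(g, merge_threshold = 1e-9)
  expect_equal(nrow(b$summary), 2)
  bm <- barrier_matrix(g, b)
  a2b <- bm$barrier[bm$from == "1" & bm$to == "2"]
  b2a <- bm$barrier[bm$from == "2" & bm$to == "1"]
  expect_equal(sort(c(a2b, b2a)), c(2, 3), tolerance = 1e-9)
})

test_that("symmetric double well has equal barriers both ways", {
  centers <- rbind(c(8, 8, 8), c(17, 17, 17))
  g <- gaussian_mixture_grid(centers, sd = 1.6)
  b <- find_basins(g)
  bm <- barrier_matrix(g, b)
  expect_equal(bm$barrier[1], bm$barrier[2], tolerance = 0.05)
})

test_that("shared-saddle identity holds on every pair", {
  set.seed(4)
  centers <- rbind(c(6, 6, 6), c(18, 18, 18), c(6, 18, 6), c(18, 6, 18))
  g <- gaussian_mixture_grid(centers, sd = 1.7,
                             weights = c(0.4, 0.3, 0.2, 0.1))
  b <- find_basins(g)
  bm <- barrier_matrix(g, b)
  um <- setNames(b$summary$U_min, as.character(b$summary$basin))
  for (i in seq_len(nrow(bm))) {
    rev <- bm[bm$from == bm$to[i] & bm$to == bm$from[i], ]
    expect_equal(bm$barrier[i] - rev$barrier,
                 um[[bm$to[i]]] - um[[bm$from[i]]], tolerance = 1e-9)
  }
})

test_that("minimax saddle search matches exhaustive enumeration on small grids", {
  set.seed(7)
  for (rep in 1:4) {
    d <- c(5, 5, 5)
    U <- array(runif(prod(d), 0, 10), d)
    # two designated minima: force them to be the smallest values
    U[1, 1, 1] <- 0; U[5, 5, 5] <- 0.1
    P <- exp(-U)
    g <- landscape_from_probability(P)
    fake_basins <- list(summary = data.frame(basin = 1:2, U_min = c(g$U[1,1,1], g$U[5,5,5])),
                        minima = c(1L, 125L))
    class(fake_basins) <- "basin_set"
    bm <- barrier_matrix(g, fake_basins)
    D <- minimax_oracle(g$U)
    expect_equal(bm$U_saddle[1], D[1, 125], tolerance = 1e-9)
    expect_equal(bm$U_saddle[2], D[125, 1], tolerance = 1e-9)
  }
})

test_that("disconnected basins give infinite barriers", {
  P <- array(0, c(5, 1, 1))
  P[1, 1, 1] <- 0.6; P[5, 1, 1] <- 0.4     # support split by a P = 0 gap
  g <- landscape_from_probability(P)
  b <- find_basins(g, merge_threshold = 1e-9)
  expect_equal(nrow(b$summary), 2)
  bm <- barrier_matrix(g, b)
  expect_true(all(is.infinite(bm$barrier)))
})

test_that("MFPT matches the exponential and linear-solve CTMC oracles", {
  # two-state: single gene, first passage 0 -> >=1 is Exp(g0)
  net <- unregulated_gene(g0 = 5, k = 1)
  nb <- 10L
  mask <- array(FALSE, rep(nb, 3))
  mask[2:10, , ] <- TRUE
  seeds <- derive_seeds(31, 200)
  times <- vapply(seeds, function(s)
    first_passage(net, c(A = 0), mask, c("A", "A", "A"), bin_width = 1,
                  n_bins = nb, seed = s, max_events = 1e5)$time, 0)
  expect_lt(abs(mean(times) - 1 / 5), 3 * sd(times) / sqrt(200))

  # linear-solve oracle: birth-death gene, passage 0 -> n >= 3
  net2 <- unregulated_gene(g0 = 2, k = 1)
  gen <- cme_generator(net2, truncation = 30)
  start <- which(gen$states$A == 0)
  targets <- which(gen$states$A >= 3)
  t_oracle <- mfpt_ctmc_oracle(gen$Q, start, targets)
  mask2 <- array(FALSE, rep(nb, 3))
  mask2[4:10, , ] <- TRUE
  times2 <- vapply(derive_seeds(77, 300), function(s)
    first_passage(net2, c(A = 0), mask2, c("A", "A", "A"), bin_width = 1,
                  n_bins = nb, seed = s, max_events = 1e6)$time, 0)
  expect_lt(abs(mean(times2) - t_oracle), 3 * sd(times2) / sqrt(300))
})

test_that("barrier_time_correlation recovers exact Arrhenius data", {
  barriers <- c(1, 2, 3, 4, 5)
  mfpts <- exp(0.5 + 1.3 * barriers)
  expect_equal(barrier_time_correlation(barriers, mfpts), 1)
  expect_equal(barrier_time_correlation(barriers, exp(-barriers)), -1)
  expect_error(barrier_time_correlation(rep(1, 5), mfpts[1:5]), "variance")
  expect_error(barrier_time_correlation(1:2, exp(1:2)))  # needs >= 3 pairs
})

test_that("path_flux follows the sequential-MFPT definition", {
  mfpts <- data.frame(from = c("N", "P", "N", "S", "C2"),
                      to = c("P", "C", "S", "C2", "C"),
                      mean = c(10, 5, 20, 40, 10))
  routes <- list(c("N", "P", "C"), c("N", "S", "C2", "C"))
  probs <- c(N = 0.5, P = 0.2, C = 0.1, S = 0.1, C2 = 0.1)
  fl <- path_flux(routes, mfpts, probs)
  expect_equal(fl$time, c(15, 70))
  expect_equal(fl$rate, 1 / c(15, 70))
  expect_equal(fl$flux, 0.5 / c(15, 70))
  expect_equal(sum(fl$probability), 1, tolerance = 1e-9)
  # dominance follows the shorter total time
  expect_gt(fl$probability[1], fl$probability[2])
  # probabilities invariant to common flux rescaling (source mass change)
  fl2 <- path_flux(routes, mfpts, c(probs["N"] * 10, probs[-1]))
  expect_equal(fl$probability, fl2$probability)
  # missing step errors with the step named
  expect_error(path_flux(list(c("N", "X", "C"), c("N", "P", "C")), mfpts, probs),
               "N->X")
  # routes must share endpoints
  expect_error(path_flux(list(c("N", "C"), c("P", "C")), mfpts, probs),
               "share")
})
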