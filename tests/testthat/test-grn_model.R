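# Network model: structure, validation, rate laws.

test_that("default network matches the published structure", {
  net <- default_network()
  expect_length(net$nodes, 6)
  expect_length(net$regulations, 16)
  signs <- vapply(net$regulations, `[[`, "", "sign")
  expect_equal(sum(signs == "activation"), 7)
  expect_equal(sum(signs == "repression"), 9)
  ids <- vapply(net$regulations, regulation_id, "")
  expect_true("miR200-|ZEB" %in% ids)
  # the three scanned key regulations are present
  expect_true(all(c("OCT4->OCT4", "P53->P53") %in% ids))
  expect_identical(validate_network(net), character(0))
})

test_that("validate_network reports violations without throwing", {
  net <- default_network()
  bad <- net
  bad$regulations[[1]]$target <- "X"
  v <- validate_network(bad)
  expect_length(v, 1)
  expect_match(v, "X")

  bad2 <- net
  bad2$regulations[[2]]$lambda <- 1.5   # activation ok
  expect_length(validate_network(bad2), 0)
  bad2$regulations[[1]]$lambda <- 1.5   # repression must be in (0,1)
  expect_match(validate_network(bad2), "lambda")

  bad3 <- net
  bad3$nodes[[1]]$g0 <- -1
  expect_match(validate_network(bad3), "g0")
})

test_that("synthesis rate multiplies per bound site", {
  p <- parameter_set()
  net <- network_spec(
    list(gene_node("A"), gene_node("B"), gene_node("C")),
    list(regulation("B", "A", "activation"),
         regulation("C", "A", "repression")),
    params = p)
  expect_equal(synthesis_rate(net, "A", c(0, 0)), 50)
  expect_equal(synthesis_rate(net, "A", c(1, 0)), 400)   # g0 * lambda_a
  expect_equal(synthesis_rate(net, "A", c(0, 1)), 25)    # g0 * lambda_r
  expect_equal(synthesis_rate(net, "A", c(1, 1)), 200)   # g0 * lambda_a * lambda_r
  expect_error(synthesis_rate(net, "A", c(1)), "occupancy length")
})

test_that("synthesis rate stays within the fold-change envelope", {
  p <- parameter_set()
  net <- network_spec(
    list(gene_node("A"), gene_node("B")),
    list(regulation("B", "A", "activation"),
         regulation("B", "A", "activation"),
         regulation("B", "A", "repression")),
    params = p)
  lo <- p$g0 * p$lambda_r
  hi <- p$g0 * p$lambda_a^2
  for (occ in asplit(expand.grid(0:1, 0:1, 0:1), 1)) {
    g <- synthesis_rate(net, "A", as.numeric(occ))
    expect_gte(g, lo); expect_lte(g, hi)
  }
})

test_that("binding propensity follows the printed multimer laws", {
  r2 <- regulation("A", "B", "activation", m = 2, h = 2, f = 1000, lambda = 8)
  expect_equal(binding_propensity(r2, 3), 2 * 3 * 2 / 2)          # 6
  r4 <- regulation("A", "B", "activation", m = 4, h = 2, f = 1000, lambda = 8)
  expect_equal(binding_propensity(r4, 3), 0)                      # n < m
  expect_equal(binding_propensity(r4, 4), 2 * 4 * 3 * 2 * 1 / 6)  # 8, divisor 6
  r1 <- regulation("A", "B", "activation", m = 1, h = 2, f = 1000, lambda = 8)
  expect_equal(binding_propensity(r1, 7), 14)
  expect_error(binding_propensity(r1, -1), "non-negative")
})

test_that("binding propensity is non-decreasing in n and zero below m", {
  for (m in c(1L, 2L, 4L)) {
    r <- regulation("A", "B", "repression", m = m, h = 1.875, f = 1000,
                    lambda = 0.5)
    n <- 0:60
    prop <- binding_propensity(r, n)
    expect_true(all(diff(prop) >= 0))
    expect_true(all(prop[n < m] == 0))
    expect_true(all(prop[n >= m] > 0))
  }
})

test_that("strength_scale multiplies the binding rate", {
  r <- regulation("A", "B", "repression", m = 2, h = 2, f = 1000, lambda = 0.5,
                  strength_scale = 1.5)
  expect_equal(binding_propensity(r, 10), 1.5 * 2 * 10 * 9 / 2)
})

test_that("unbinding rate and derived constants follow f = k * omega", {
  expect_equal(unbinding_rate(regulation("A","B","activation"),
                              parameter_set(k = 1, omega = 1000)), 1000)
  expect_equal(unbinding_rate(regulation("A","B","activation"),
                              parameter_set(k = 1, omega = 1)), 1)
  expect_equal(unbinding_rate(regulation("A","B","activation"),
                              parameter_set(k = 2, omega = 1000)), 2000)
  # per-regulation override wins
  r <- regulation("A", "B", "activation", f = 123)
  expect_equal(unbinding_rate(r, parameter_set()), 123)
  p <- parameter_set()
  expect_equal(p$Xeq_a, 500)
  expect_equal(p$Xeq_r, 1000 / 1.875)
})

test_that("network config files round-trip", {
  net <- default_network()
  f <- tempfile(fileext = ".json")
  write_network_config(net, f)
  net2 <- read_network_config(f)
  expect_identical(validate_network(net2), character(0))
  expect_equal(network_table(net2), network_table(net))
  expect_equal(net2$params$omega, 1000)
})
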