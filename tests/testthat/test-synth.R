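test_that("noiseless interaction-free generation is exactly invertible", {
  cfg <- generator_config(25, 6, d = 0, noise = list(sigma_log = 0), seed = 91)
  sim <- generate_abundance(cfg)
  expect_equal(sim$abund$values, sim$truth$independent,
               ignore_attr = TRUE, tolerance = 1e-12)
  for (j in 1:6) {
    f <- fit_power(sim$abund$values[, j], sim$truth$H)
    expect_equal(f$alpha, sim$truth$alpha[j], tolerance = 1e-6)
    expect_equal(f$beta, sim$truth$beta[j], tolerance = 1e-6)
  }
})

test_that("generation is a pure function of the seed", {
  cfg <- generator_config(20, 8, d = 2, seed = 92)
  s1 <- generate_abundance(cfg)
  s2 <- generate_abundance(cfg)
  expect_identical(s1$abund$values, s2$abund$values)
  expect_identical(s1$truth$adjacency, s2$truth$adjacency)
})

test_that("truth components satisfy additivity and record the H discrepancy", {
  sim <- generate_abundance(generator_config(20, 6, d = 2, seed = 93))
  expect_equal(sim$truth$independent + sim$truth$dependent,
               sim$truth$signal, tolerance = 1e-12)
  expect_length(sim$truth$habitat_discrepancy, 20)
  # realized habitat index = drawn H + recorded discrepancy
  expect_equal(unname(rowSums(sim$abund$values)),
               unname(sim$truth$H + sim$truth$habitat_discrepancy),
               tolerance = 1e-9)
})

test_that("the planted network is acyclic and respects d", {
  sim <- generate_abundance(generator_config(30, 10, d = 3, seed = 94))
  adj <- sim$truth$adjacency[[1]]
  g <- igraph::graph_from_data_frame(adj[, c("from", "to")])
  expect_true(igraph::is_dag(g))
  expect_true(all(table(adj$to) <= 3))
})

test_that("scenarios mirror the study dimensions", {
  s1 <- generate_abundance(scenario("phylum17", seed = 1))
  expect_equal(dim(s1$abund), c(23L, 17L))
  s2 <- generate_abundance(scenario("species65_7mod", seed = 1))
  expect_equal(ncol(s2$abund$values), 65L)
  expect_equal(length(unique(s2$truth$modules)), 7L)
  s3 <- generate_abundance(scenario("two_context", seed = 1))
  expect_equal(as.integer(table(s3$abund$context)[c("UC", "HC")]), c(19L, 4L))
  expect_error(scenario("nope"), "arg")
})

test_that("a seed is mandatory and context sizes must be consistent", {
  expect_error(generator_config(10, 5), "seed")
  expect_error(generator_config(10, 5, contexts = list(sizes = c(4, 4)),
                                seed = 1), "sum")
})

test_that("snr calibration sets the noise level from the planted strengths", {
  cfg <- generator_config(40, 8, d = 2, noise = list(snr = 5), seed = 95)
  sim <- generate_abundance(cfg)
  expect_equal(sim$truth$sigma_log,
               sqrt(2) * mean(cfg$strength_range) / 5, tolerance = 1e-12)
})
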