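test_that("exact power-law data are recovered exactly", {
  H <- exp(seq(log(10), log(1000), length.out = 20))
  f <- fit_power(H, H)            # y = H: alpha 1, beta 1
  expect_equal(f$alpha, 1, tolerance = 1e-10)
  expect_equal(f$beta, 1, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("constant abundance gives a flat fit with unit R2", {
  H <- exp(seq(log(10), log(1000), length.out = 15))
  f <- fit_power(rep(5, 15), H)
  expect_equal(f$beta, 0, tolerance = 1e-12)
  expect_equal(f$alpha, 5, tolerance = 1e-12)
  expect_equal(f$r2, 1)
})

test_that("noisy fits agree with an independent grid-search oracle", {
  set.seed(11)
  H <- exp(runif(50, log(10), log(1000)))
  y <- 0.35 * H^1.2 * exp(rnorm(50, 0, 0.1))
  f <- fit_power(y, H)
  expect_lt(abs(f$beta - 1.2), 0.05)
  # oracle: 2-D grid search over (log alpha, beta) on log-scale SSE
  sse <- function(a, b) sum((log(y) - a - b * log(H))^2)
  # coarse-to-fine 2-D grid search, final resolution 5e-4
  ctr <- c(log(0.35), 1.2)
  for (span in c(0.4, 0.1, 0.01)) {
    grid_a <- seq(ctr[1] - span, ctr[1] + span, length.out = 81)
    grid_b <- seq(ctr[2] - span, ctr[2] + span, length.out = 81)
    vals <- outer(grid_a, grid_b, Vectorize(sse))
    best <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(grid_a[best[1]], grid_b[best[2]])
  }
  expect_lt(abs(ctr[1] - log(f$alpha)), 1e-3)
  expect_lt(abs(ctr[2] - f$beta), 1e-3)
})

test_that("the log-log fit is scale-equivariant", {
  set.seed(4)
  H <- exp(runif(30, log(10), log(1000)))
  y <- 2 * H^0.7 * exp(rnorm(30, 0, 0.2))
  f1 <- fit_power(y, H)
  f2 <- fit_power(10 * y, H)
  expect_equal(f2$alpha, 10 * f1$alpha, tolerance = 1e-10)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("nls refinement never worsens the original-scale objective", {
  set.seed(5)
  H <- exp(runif(40, log(10), log(1000)))
  y <- 0.5 * H^1.1 * exp(rnorm(40, 0, 0.3))
  fl <- fit_power(y, H, method = "loglog")
  fn <- fit_power(y, H, method = "nls")
  obj <- function(f) sum((y - f$alpha * H^f$beta)^2)
  expect_lte(obj(fn), obj(fl) + 1e-8)
})

test_that("preconditions are enforced", {
  expect_error(fit_power(c(0, 0, 0, 1, 2), exp(1:5)), "insufficient")
  expect_error(fit_power(1:3, c(-1, 2, 3)), "positive")
  f <- fit_power(exp(1:5), exp(1:5))
  expect_error(predict(f, c(1, -2)), "positive")
})

test_that("predictions follow the fitted law", {
  f <- structure(list(alpha = 1, beta = 1), class = "power_fit")
  expect_equal(predict(f, c(2, 3)), c(2, 3))
  f0 <- structure(list(alpha = 4, beta = 0), class = "power_fit")
  expect_equal(predict(f0, c(2, 9)), c(4, 4))
  fp <- structure(list(alpha = 2, beta = 0.5), class = "power_fit")
  H <- seq(1, 100, length.out = 50)
  expect_true(all(diff(predict(fp, H)) > 0))
})

test_that("fit_power_all recovers a noiseless generator exactly", {
  sim <- generate_abundance(generator_config(30, 8, d = 0,
                                             noise = list(sigma_log = 0),
                                             seed = 21))
  pf <- fit_power_all(sim$abund)
  # the realized habitat index differs from the drawn one, so refit
  # against the drawn H for exact inversion
  for (j in seq_along(pf)) {
    f <- fit_power(sim$abund$values[, j], sim$truth$H)
    expect_equal(f$alpha, sim$truth$alpha[j], tolerance = 1e-6)
    expect_equal(f$beta, sim$truth$beta[j], tolerance = 1e-6)
  }
})

test_that("a decreasing taxon's negative exponent is recovered among increasing ones", {
  set.seed(31)
  cfg <- generator_config(40, 6, d = 0, beta = c(-0.6, 0.8, 1.1, 0.5, 1.3, 0.9),
                          noise = list(sigma_log = 0.15), seed = 31)
  sim <- generate_abundance(cfg)
  pf <- fit_power_all(sim$abund)
  betas <- vapply(pf, function(f) f$beta, 0)
  expect_lt(betas[1], 0)
  expect_true(all(betas[-1] > 0))
})

test_that("all-equal columns give flat exponents across taxa", {
  V <- matrix(rep(c(1, 2, 4, 8, 16), 3), 5, 3)
  rownames(V) <- paste0("s", 1:5)
  M <- abundance_matrix(V)
  pf <- fit_power_all(M)
  # every column equals a third of the habitat index: beta = 1
  for (f in pf) expect_equal(f$beta, 1, tolerance = 1e-10)
})
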