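test_that("the decomposition is additive to machine precision", {
  sim <- generate_abundance(generator_config(30, 6, d = 2, seed = 61))
  M <- sim$abund
  fit <- qdnet(M, order = 2)
  for (f in fit$ode_fits) {
    dep <- Reduce(`+`, c(list(rep(0, length(f$grid))), f$dependent_traj))
    err <- max(abs(f$fitted - (f$independent_traj + dep)))
    expect_lt(err / max(abs(f$fitted)), 1e-9)
  }
})

test_that("an isolated taxon reproduces its noiseless curve", {
  sim <- generate_abundance(generator_config(30, 10, d = 0,
                                             noise = list(sigma_log = 0),
                                             seed = 62))
  M <- sim$abund
  ode <- fit_qdode(M, empty_links(M), order = 3)
  for (f in ode) {
    expect_length(f$dependent_traj, 0)
    r2 <- 1 - sum((f$observed - f$fitted)^2) /
      sum((f$observed - mean(f$observed))^2)
    expect_gte(r2, 0.99)
  }
})

test_that("trajectories are integrals of their Q terms (step-halving check)", {
  sim <- generate_abundance(generator_config(25, 4, d = 1, seed = 63))
  M <- sim$abund
  pf <- fit_power_all(M)
  links <- select_links(M, order = 2, fits = pf)
  # smoothed Q arguments: the integrands are smooth, so halving the RK4
  # step must leave the trajectories essentially unchanged
  o1 <- fit_qdode(M, links, order = 2, fits = pf, nsub = 8,
                  predictor = "smoothed")
  o2 <- fit_qdode(M, links, order = 2, fits = pf, nsub = 16,
                  predictor = "smoothed")
  for (tx in taxa(M)) {
    sc <- max(abs(o1[[tx]]$fitted))
    expect_lt(max(abs(o1[[tx]]$fitted - o2[[tx]]$fitted)) / sc, 1e-6)
  }
})

test_that("a planted signed influence is recovered with the right direction", {
  ok <- logical(0)
  r2s <- numeric(0)
  for (sd_ in 1:10) {
    set.seed(sd_)
    sim <- generate_abundance(generator_config(50, 4, d = 0,
                                               noise = list(sigma_log = 0.1),
                                               seed = sd_ + 70))
    sgn <- sample(c(-1, 1), 1)
    M <- plant_edge(sim$abund, "T01", "T02", strength = 1, sign = sgn)
    pf <- fit_power_all(M)
    links <- empty_links(M)
    links$T01$selected <- "T02"
    ode <- fit_qdode(M, links, order = 3, fits = pf)
    net <- build_network(ode)
    e <- net$edges
    es <- e$sign[e$from == "T02" & e$to == "T01"]
    # neutral-thresholded edges are "not recovered", not sign errors
    if (es != 0) ok <- c(ok, es == sgn)
    f <- ode[["T01"]]
    r2s <- c(r2s, 1 - sum((f$observed - f$fitted)^2) /
               sum((f$observed - mean(f$observed))^2))
  }
  expect_gte(length(ok), 5)
  expect_gte(mean(ok), 0.8)
  expect_gte(stats::median(r2s), 0.3)
})

test_that("decompose splits promotion and inhibition totals correctly", {
  sim <- generate_abundance(generator_config(20, 4, d = 0, seed = 64))
  M <- sim$abund
  ode <- fit_qdode(M, empty_links(M), order = 2)
  d <- decompose(ode[[1]])
  expect_true(all(d$dependent_pos == 0))
  expect_true(all(d$dependent_neg == 0))
  # a fabricated single-partner fit with an everywhere-positive trajectory
  f <- ode[[1]]
  f$dependent_traj <- list(T02 = abs(sin(seq_along(f$grid))) + 0.1)
  f$fitted <- f$independent_traj + f$dependent_traj$T02
  d2 <- decompose(f)
  expect_true(all(d2$dependent_neg == 0))
  expect_equal(d2$dependent_pos, f$dependent_traj$T02)
})

test_that("the block-covariance log-likelihood matches a dense oracle", {
  set.seed(65)
  n <- 4; m <- 3
  R <- matrix(rnorm(n * m), n, m)
  fits <- structure(lapply(seq_len(m), function(j)
    structure(list(observed = R[, j], fitted = rep(0, n)),
              class = "qdode_fit")), names = paste0("T", 1:m),
    class = "qdode_fit_list")
  S <- crossprod(R) / n + diag(0.5, m)
  ll <- qdode_loglik(fits, S)
  # dense oracle: full nm x nm normal density with Sigma = S (x) I_n
  Sig <- kronecker(S, diag(n))
  r <- as.vector(R)
  ll_dense <- -0.5 * (length(r) * log(2 * pi) +
                      determinant(Sig)$modulus +
                      drop(r %*% solve(Sig, r)))
  expect_equal(ll, as.numeric(ll_dense), tolerance = 1e-8)
})

test_that("independent errors reduce to summed univariate log-likelihoods", {
  set.seed(66)
  n <- 6; m <- 3
  R <- matrix(rnorm(n * m), n, m)
  fits <- structure(lapply(seq_len(m), function(j)
    structure(list(observed = R[, j], fitted = rep(0, n)),
              class = "qdode_fit")), names = paste0("T", 1:m),
    class = "qdode_fit_list")
  s2 <- colMeans(R^2)
  ll <- qdode_loglik(fits, diag(s2, m))
  ll_uni <- sum(vapply(seq_len(m), function(j)
    sum(stats::dnorm(R[, j], 0, sqrt(s2[j]), log = TRUE)), 0))
  expect_equal(ll, ll_uni, tolerance = 1e-10)
})

test_that("zero residuals with unit variances give the closed form", {
  n <- 5; m <- 2
  fits <- structure(lapply(seq_len(m), function(j)
    structure(list(observed = rep(1, n), fitted = rep(1, n)),
              class = "qdode_fit")), names = paste0("T", 1:m),
    class = "qdode_fit_list")
  ll <- qdode_loglik(fits, diag(1, m))
  expect_equal(ll, -(n * m / 2) * log(2 * pi))
})

test_that("duplicate habitat indices are perturbed with a warning", {
  V <- matrix(rexp(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  V[2, ] <- V[1, ]                       # two identical samples
  M <- abundance_matrix(V)
  expect_warning(fit_qdode(M, empty_links(M), order = 1), "perturbed")
})
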