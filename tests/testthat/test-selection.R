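test_that("order-0 blocks collapse to single columns and maps hit the endpoints", {
  sim <- generate_abundance(generator_config(20, 5, d = 0, seed = 51))
  M <- sim$abund
  d0 <- build_design(M, taxa(M)[1], order = 0)
  expect_true(all(vapply(d0$blocks, ncol, 0L) == 1L))
  d3 <- build_design(M, taxa(M)[1], order = 3)
  for (B in d3$blocks) {
    # the mapped variable hits -1 and +1 exactly at its extremes
    expect_equal(min(B[, 2]), -max(B[, 2]), tolerance = 1e-9)
  }
  expect_equal(unname(d3$z[1]), 0)
  expect_equal(unname(d3$z[length(d3$z)]), 0)
})

test_that("a lambda above lambda_max selects nothing", {
  sim <- generate_abundance(generator_config(25, 6, d = 0, seed = 52))
  d <- build_design(sim$abund, "T01", order = 2)
  s <- group_lasso(d, lambda = c(1e6, 1e5))
  expect_length(s$selected, 0)
})

test_that("a planted single signal among decoys is recovered", {
  set.seed(53)
  sim <- generate_abundance(generator_config(40, 6, d = 0,
                                             noise = list(sigma_log = 0.1),
                                             seed = 53))
  M <- plant_edge(sim$abund, "T01", "T04", strength = 1.5)
  pf <- fit_power_all(M)
  d <- build_design(M, "T01", order = 3, fits = pf)
  s1 <- group_lasso(d)
  s2 <- adaptive_group_lasso(d, s1)
  expect_identical(s2$selected, "T04")
})

test_that("the active set is monotone along the converged lambda path", {
  set.seed(54)
  sim <- generate_abundance(generator_config(30, 8, d = 2, seed = 54))
  d <- build_design(sim$abund, "T02", order = 2)
  s <- group_lasso(d)
  p <- s$path[!is.na(s$path$crit) & s$path$converged, ]
  expect_true(all(diff(p$active[order(-p$lambda)]) >= 0))
})

test_that("the solution objective never exceeds the zero solution", {
  set.seed(55)
  sim <- generate_abundance(generator_config(30, 6, d = 1, seed = 55))
  d <- build_design(sim$abund, "T03", order = 2)
  a0 <- stats::lm.wfit(d$self_block, d$y, pmax(d$z, 1e-12))
  obj0 <- sum(d$z * a0$residuals^2)
  s <- group_lasso(d)
  k <- which(!is.na(s$path$crit) & s$path$converged)
  expect_true(all(s$path$rss[k] <= obj0 + 1e-8))
})

test_that("singleton-group selection agrees with a glmnet lasso oracle", {
  skip_if_not_installed("glmnet")
  set.seed(56)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  y <- drop(X[, c(2, 5)] %*% c(1.5, -2)) + rnorm(n, 0, 0.3)
  blocks <- lapply(seq_len(8), function(j) X[, j, drop = FALSE])
  names(blocks) <- paste0("P", 1:8)
  # unscaled singleton blocks so the penalty matches glmnet exactly
  design <- list(focal = "f", y = y, H = seq_len(n), z = rep(1, n),
                 self_block = matrix(1, n, 1), blocks = blocks,
                 scales = rep(1, 8), order = 0, constant = rep(FALSE, 8))
  s <- group_lasso(design, lambda_min_ratio = 1e-3)
  g <- glmnet::glmnet(X, y, intercept = TRUE, standardize = FALSE)
  # compare supports at matched penalties: ours lambda ~ 2 n lambda_glmnet
  for (k in c(10, 25, 40)) {
    lam <- s$path$lambda[k]
    if (is.na(s$path$crit[k]) || !s$path$converged[k]) next
    sol <- qdnet:::.bcd_group_lasso(y, design$self_block, design$blocks,
                                    design$z, lam)
    ours <- which(vapply(sol$beta, function(b) any(abs(b) > 1e-8), TRUE))
    cf <- glmnet::coef.glmnet(g, s = lam / (2 * n), exact = TRUE,
                              x = X, y = y)
    theirs <- which(abs(cf[-1]) > 1e-8)
    # scale for our standardized blocks: support comparison only
    expect_identical(unname(ours), unname(theirs))
  }
})

test_that("an empty stage-1 screen returns an empty final selection", {
  set.seed(57)
  sim <- generate_abundance(generator_config(20, 5, d = 0, seed = 57))
  d <- build_design(sim$abund, "T01", order = 2)
  s1 <- group_lasso(d, lambda = c(1e7, 1e6))
  expect_length(s1$selected, 0)
  s2 <- adaptive_group_lasso(d, s1)
  expect_length(s2$selected, 0)
  expect_identical(s2$stage, "adaptive")
})

test_that("adaptive weights favor strong stage-1 groups", {
  set.seed(60)
  sim <- generate_abundance(generator_config(40, 6, d = 0,
                                             noise = list(sigma_log = 0.1),
                                             seed = 60))
  M <- plant_edge(sim$abund, "T01", "T05", strength = 1.5)
  pf <- fit_power_all(M)
  d <- build_design(M, "T01", order = 2, fits = pf)
  s1 <- group_lasso(d)
  s2 <- adaptive_group_lasso(d, s1)
  w <- s2$weights
  names(w) <- names(d$blocks)
  expect_true(is.finite(w[["T05"]]))
  expect_true("T05" %in% s2$selected)
})

test_that("max_links caps the partner count", {
  set.seed(59)
  sim <- generate_abundance(generator_config(40, 8, d = 3, seed = 59))
  links <- select_links(sim$abund, order = 2, max_links = 1)
  expect_true(all(vapply(links, function(s) length(s$selected), 0L) <= 1L))
})
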