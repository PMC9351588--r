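test_that("two planted curve families are separated perfectly", {
  set.seed(41)
  H <- exp(runif(30, log(10), log(1000)))
  mk <- function(a, b, k) vapply(seq_len(k), function(i)
    a * H^b * exp(rnorm(30, 0, 0.05)), numeric(30))
  V <- cbind(mk(1, 1.2, 8), mk(5, 0.2, 8))
  colnames(V) <- sprintf("t%02d", 1:16); rownames(V) <- sprintf("s%02d", 1:30)
  M <- abundance_matrix(V)
  cl <- functional_cluster(M, 2, seed = 1)
  expect_equal(ari(cl$labels, rep(1:2, each = 8)), 1)
  expect_true(all(abs(rowSums(cl$posterior) - 1) < 1e-12))
})

test_that("a single module reduces to the pooled log-log fit", {
  sim <- generate_abundance(generator_config(25, 6, d = 0,
                                             noise = list(sigma_log = 0.1),
                                             seed = 42))
  M <- sim$abund
  cl <- functional_cluster(M, 1, seed = 1)
  expect_true(all(cl$posterior == 1))
  # pooled fit: log-log regression of the mean log profile
  lH <- log(habitat_index(M))
  xbar <- rowMeans(log(M$values))
  b <- stats::cov(lH, xbar) / stats::var(lH)
  a <- mean(xbar) - b * mean(lH)
  expect_equal(cl$module_params$beta, b, tolerance = 1e-8)
  expect_equal(log(cl$module_params$alpha), a, tolerance = 1e-8)
})

test_that("duplicated taxa are co-assigned", {
  sim <- generate_abundance(generator_config(20, 6, d = 0, seed = 43))
  V <- sim$abund$values
  V <- cbind(V, dup = V[, 3])
  M <- abundance_matrix(V)
  cl <- functional_cluster(M, 2, seed = 2)
  expect_equal(unname(cl$labels["dup"]), unname(cl$labels[3]))
})

test_that("the EM log-likelihood is monotone non-decreasing", {
  sim <- generate_abundance(generator_config(25, 12, n_modules = 2, d = 0,
                                             noise = list(sigma_log = 0.2),
                                             seed = 44))
  cl <- functional_cluster(sim$abund, 2, seed = 1, n_starts = 1)
  expect_true(all(diff(cl$trace) >= -1e-8 * (abs(cl$trace[-1]) + 1)))
})

test_that("BIC chooses one module for single-curve data", {
  sim <- generate_abundance(generator_config(30, 10, n_modules = 1, d = 0,
                                             beta = 0.8, alpha = 1,
                                             noise = list(sigma_log = 0.1),
                                             seed = 45))
  sl <- select_L(sim$abund, L_max = 3, seed = 1, n_starts = 2)
  expect_equal(sl$L, 1L)
  expect_true(all(is.finite(sl$bic_path$bic[!is.na(sl$bic_path$bic)])))
})

test_that("module profiles are arithmetic means that preserve the community mean", {
  sim <- generate_abundance(generator_config(15, 9, n_modules = 3, d = 0,
                                             seed = 46))
  M <- sim$abund
  cl <- functional_cluster(M, 3, seed = 1)
  prof <- module_profiles(M, cl)
  sizes <- table(cl$labels)
  # size-weighted mean of module profiles == overall mean abundance
  w <- as.numeric(sizes[sub("module", "", taxa(prof))])
  expect_equal(drop(prof$values %*% w) / sum(w),
               rowMeans(M$values), tolerance = 1e-12)
  # singleton module equals its column
  one <- names(cl$labels)[cl$labels == cl$labels[1]][1]
  Mone <- M[, c(one, names(cl$labels)[cl$labels != cl$labels[1]][1])]
  a2 <- structure(list(labels = stats::setNames(c(1L, 2L), taxa(Mone))),
                  class = "module_assignment")
  p2 <- module_profiles(Mone, a2)
  expect_equal(unname(p2$values[, 1]), unname(Mone$values[, 1]))
})

test_that("oversized modules are split recursively into tractable ones", {
  sim <- generate_abundance(generator_config(30, 24, n_modules = 2, d = 0,
                                             noise = list(sigma_log = 0.1),
                                             seed = 47))
  cl <- functional_cluster(sim$abund, 1, seed = 1)   # everything in one module
  lab <- refine_modules(sim$abund, cl, max_size = 15, seed = 1)
  expect_true(all(table(lab) <= 15))
  expect_gte(length(unique(lab)), 2L)
})
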