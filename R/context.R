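# Context comparison: does network structure differ among C contexts
# (e.g. diseased vs healthy)? Null model: one pooled qdODE fit; alternative:
# per-context coefficient sets Theta^c on the SAME link support (selected
# once on pooled data, so the permutation stays exchangeable on one model
# class). LR = -2 (log L_null - log L_alt), calibrated by permuting the
# context labels while preserving group sizes.

# Gaussian log-likelihood of a residual matrix under the independence
# working model (diagonal covariance, per-taxon variances at their MLE).
# The full block covariance of the joint likelihood is nearly singular at
# per-context sample sizes comparable to the taxon count, which would let
# covariance overfit dominate the LR; the diagonal working model keeps
# the statistic driven by the mean (network) structure. The permutation
# calibration is exact either way.
.gauss_ll <- function(R) {
  n <- nrow(R)
  s2 <- pmax(colMeans(R^2), 1e-300)
  sum(-(n / 2) * (log(2 * pi * s2) + 1))
}

# Shared precomputation: pooled power fits, pooled link support, and per
# focal taxon the full-grid cumulative design (subset fits reuse it).
.context_prepare <- function(M, contexts, order = 3, fits = NULL,
                             links = NULL, weights = "parabolic",
                             nsub = 8, predictor = "observed") {
  stopifnot(inherits(M, "abund"))
  contexts <- as.character(contexts)
  if (length(contexts) != nrow(M$values))
    stop("one context label per sample required")
  cnt <- table(contexts)
  if (length(cnt) < 2) stop("need at least 2 contexts")
  if (any(cnt < 3))
    stop("context too small to fit: ",
         paste(names(cnt)[cnt < 3], collapse = ", "))
  if (is.null(fits)) fits <- fit_power_all(M)
  if (is.null(links)) links <- select_links(M, order = order, fits = fits,
                                            weights = weights)
  H <- habitat_index(M)
  ord <- order(H)
  grid <- .strict_grid(H[ord])
  Y <- M$values[ord, , drop = FALSE]
  designs <- lapply(taxa(M), function(tx)
    .qdode_design_taxon(tx, intersect(links[[tx]]$selected, taxa(M)),
                        fits, grid, order, nsub, Y = Y,
                        predictor = predictor))
  names(designs) <- taxa(M)
  yhat <- vapply(taxa(M), function(tx)
    smoothed_abundance(fits[[tx]], grid), numeric(length(grid)))
  list(M = M, grid = grid, Y = Y, yhat = yhat,
       contexts = contexts[ord], designs = designs, weights = weights,
       links = links, fits = fits)
}

# Residual matrix from refitting every taxon's Theta on the samples in idx
# (increasing positions on the pooled sorted grid).
.residuals_subset <- function(prep, idx) {
  vapply(names(prep$designs), function(tx) {
    d <- prep$designs[[tx]]
    s <- .qdode_solve(d$F, d$cols, prep$Y[, tx], prep$grid, idx,
                      prep$weights, wscale = prep$yhat[, tx])
    s$observed - s$fitted
  }, numeric(length(idx)))
}

.lr_from_labels <- function(prep, labels) {
  ll_alt <- sum(vapply(unique(labels), function(cc) {
    .gauss_ll(.residuals_subset(prep, which(labels == cc)))
  }, 0))
  lr <- -2 * (prep$ll_null - ll_alt)
  max(lr, 0)
}

#' Likelihood-ratio statistic for context-dependent network structure
#'
#' L_null comes from one pooled qdODE fit over all samples; L_alt is the
#' sum of per-context log-likelihoods with context-specific coefficient
#' sets on the shared, pooled-selected link support. LR = -2 (log L_null -
#' log L_alt); tiny negative values from the boundary initial-condition
#' convention are floored at 0 with a warning.
#'
#' @param M an `abund` object
#' @param contexts per-sample labels (C >= 2, each with >= 3 samples);
#'   defaults to `M$context`
#' @param order LOP degree
#' @param fits,links optional precomputed power fits / pooled selection
#' @param weights weight-function type for the context fits; default
#'   `"none"` so that weighted least squares coincides with the Gaussian
#'   MLE and the per-context model properly nests the pooled one
#' @return the LR statistic (non-negative scalar)
#' @export
lr_statistic <- function(M, contexts = M$context, order = 3, fits = NULL,
                         links = NULL, weights = c("none", "parabolic")) {
  weights <- match.arg(weights)
  prep <- .context_prepare(M, contexts, order, fits, links, weights)
  prep$ll_null <- .gauss_ll(.residuals_subset(prep, seq_along(prep$grid)))
  lr <- -2 * (prep$ll_null - sum(vapply(unique(prep$contexts), function(cc)
    .gauss_ll(.residuals_subset(prep, which(prep$contexts == cc))), 0)))
  if (lr < 0) {
    if (lr < -1e-4) warning(sprintf("negative LR (%.3g) floored at 0", lr))
    lr <- 0
  }
  lr
}

#' Permutation test for context-specific networks
#'
#' Reshuffles the context labels uniformly at random (group sizes
#' preserved) and recomputes the LR with the identical configuration. The
#' critical threshold is the nearest-rank 95th percentile of the null LRs;
#' the p-value uses the add-one convention (1 + #\{null >= observed\}) /
#' (n_perm + 1).
#'
#' @inheritParams lr_statistic
#' @param n_perm number of permutations (>= 100; the method's reference
#'   protocol uses 1000)
#' @param seed RNG seed (fixed seed gives bit-identical null distributions)
#' @return class `"context_test"`: `lr`, `null_lrs`, `threshold95`,
#'   `pvalue`, `n_perm`, `seed`, `per_context` summaries
#' @export
permutation_test <- function(M, contexts = M$context, n_perm = 1000,
                             seed = 1, order = 3, fits = NULL, links = NULL,
                             weights = c("none", "parabolic")) {
  weights <- match.arg(weights)
  if (n_perm < 100) stop("n_perm must be at least 100")
  prep <- .context_prepare(M, contexts, order, fits, links, weights)
  prep$ll_null <- .gauss_ll(.residuals_subset(prep, seq_along(prep$grid)))
  obs <- .lr_from_labels(prep, prep$contexts)
  set.seed(seed)
  null_lrs <- vapply(seq_len(n_perm), function(b) {
    tryCatch(.lr_from_labels(prep, sample(prep$contexts)),
             error = function(e) NA_real_)
  }, 0)
  failed <- sum(is.na(null_lrs))
  if (failed > 0.05 * n_perm)
    stop(sprintf("%d of %d permutations failed", failed, n_perm))
  null_ok <- null_lrs[!is.na(null_lrs)]
  thr <- sort(null_ok)[ceiling(0.95 * length(null_ok))]  # nearest rank
  pval <- (1 + sum(null_ok >= obs)) / (length(null_ok) + 1)
  per_context <- lapply(split(seq_along(prep$contexts), prep$contexts),
                        function(ix) {
    R <- .residuals_subset(prep, sort(ix))
    list(n = length(ix), sigma2 = colMeans(R^2))
  })
  structure(list(lr = obs, null_lrs = null_lrs, threshold95 = thr,
                 pvalue = pval, n_perm = n_perm, seed = seed,
                 n_failed = failed, per_context_fits = per_context),
            class = "context_test")
}

#' @export
print.context_test <- function(x, ...) {
  cat(sprintf("Context LR test: LR = %.4g, 95%% null threshold = %.4g, p = %.4g (%d permutations)\n",
              x$lr, x$threshold95, x$pvalue, x$n_perm))
  cat(if (x$lr > x$threshold95)
    "Network structure differs among contexts at the 5% level.\n"
  else "No evidence of context-dependent network structure.\n")
  invisible(x)
}
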