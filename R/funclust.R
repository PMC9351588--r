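# Functional clustering of taxa into modules: a taxon's log-abundance
# profile across the n samples follows a mixture over modules l of
# Gaussians with power-curve mean log(alpha_l) + beta_l log(H) and
# spherical variance sigma_l^2 (abundance noise is multiplicative, so the
# mixture lives on the log scale, where a power curve is a straight line
# in log H and the M-step is a closed-form weighted linear regression).
# EM alternates responsibilities with exact pi / (alpha, beta) / sigma^2
# updates, so the log-likelihood is monotone by construction.

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Cluster taxa into modules by power-curve mixtures (EM)
#'
#' @param M an `abund` object
#' @param L number of modules (>= 1, <= number of taxa)
#' @param seed RNG seed governing initialization
#' @param n_starts restarts (best log-likelihood wins)
#' @param tol EM convergence tolerance on the log-likelihood
#' @param max_iter EM iteration cap
#' @return class `"module_assignment"`: `labels` (named, argmax posterior,
#'   ties to the lowest module index), `L`, `module_params` (alpha, beta,
#'   sigma2, pi per module; sigma2 on the log scale), `loglik`, `bic`
#'   (penalty `(4L - 1) log(nm)`), `posterior` (taxa x L)
#' @export
functional_cluster <- function(M, L, seed = 1, n_starts = 3, tol = 1e-6,
                               max_iter = 200) {
  stopifnot(inherits(M, "abund"), L >= 1, L <= ncol(M$values))
  V <- M$values
  pos <- V[V > 0]
  if (!length(pos)) stop("no positive abundance")
  X <- t(log(pmax(V, 0.5 * min(pos))))      # taxa x samples, log scale
  lH <- log(habitat_index(M))
  m <- nrow(X); n <- ncol(X)
  var_floor <- 1e-8 * max(stats::var(as.vector(X)), 1e-300)
  # per-taxon log-log fits provide the initialization features
  sxx <- sum((lH - mean(lH))^2)
  feat_b <- drop((X - rowMeans(X)) %*% (lH - mean(lH))) / sxx
  feat_a <- rowMeans(X) - feat_b * mean(lH)
  feat_s <- scale(cbind(feat_a, feat_b))
  feat_s[!is.finite(feat_s)] <- 0
  wfit_line <- function(xbar) {
    b <- sum((lH - mean(lH)) * (xbar - mean(xbar))) / sxx
    c(a = mean(xbar) - b * mean(lH), b = b)
  }
  run_em <- function(start_seed) {
    set.seed(start_seed)
    km <- if (L == 1) list(cluster = rep(1L, m))
          else tryCatch(stats::kmeans(feat_s, centers = L, nstart = 5),
                        error = function(e)
                          list(cluster = sample(rep_len(seq_len(L), m))))
    params <- lapply(seq_len(L), function(l) {
      members <- which(km$cluster == l)
      if (!length(members)) members <- sample.int(m, max(2, m %/% L))
      cf <- wfit_line(colMeans(X[members, , drop = FALSE]))
      mu <- cf["a"] + cf["b"] * lH
      s2 <- max(mean((t(X[members, , drop = FALSE]) - mu)^2), var_floor)
      list(a = unname(cf["a"]), b = unname(cf["b"]), sigma2 = s2,
           pi = length(members) / m)
    })
    ll_old <- -Inf
    ll_trace <- numeric(0)
    tau <- NULL
    for (it in seq_len(max_iter)) {
      logd <- vapply(params, function(p) {
        mu <- p$a + p$b * lH
        log(p$pi) - (n / 2) * log(2 * pi * p$sigma2) -
          colSums((t(X) - mu)^2) / (2 * p$sigma2)
      }, numeric(m))
      logd <- matrix(logd, nrow = m)
      ll <- sum(apply(logd, 1, .logsumexp))
      ll_trace <- c(ll_trace, ll)
      tau <- exp(logd - apply(logd, 1, .logsumexp))
      pis <- colMeans(tau)
      if (any(pis < 1e-6)) return(list(degenerate = TRUE))
      params <- lapply(seq_len(L), function(l) {
        w <- tau[, l]
        cf <- wfit_line(colSums(X * w) / sum(w))
        mu <- cf["a"] + cf["b"] * lH
        s2 <- max(sum(w * colSums((t(X) - mu)^2)) / (n * sum(w)), var_floor)
        list(a = unname(cf["a"]), b = unname(cf["b"]), sigma2 = s2,
             pi = pis[l])
      })
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
      ll_old <- ll
    }
    list(degenerate = FALSE, params = params, loglik = ll, tau = tau,
         trace = ll_trace, iterations = it)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    r <- run_em(seed + s - 1L)
    if (isTRUE(r$degenerate)) next
    if (is.null(best) || r$loglik > best$loglik) best <- r
  }
  if (is.null(best))
    stop("all EM restarts degenerated (a module emptied); reduce L")
  labels <- apply(best$tau, 1, which.max)     # ties -> lowest index
  names(labels) <- rownames(X)
  p <- 4 * L - 1
  mp <- data.frame(module = seq_len(L),
                   alpha = exp(vapply(best$params, `[[`, 0, "a")),
                   beta = vapply(best$params, `[[`, 0, "b"),
                   sigma2 = vapply(best$params, `[[`, 0, "sigma2"),
                   pi = vapply(best$params, `[[`, 0, "pi"))
  structure(list(labels = labels, L = L, module_params = mp,
                 loglik = best$loglik,
                 bic = -2 * best$loglik + p * log(n * m),
                 posterior = best$tau, trace = best$trace),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("Functional clustering: %d modules over %d taxa (BIC %.2f)\n",
              x$L, length(x$labels), x$bic))
  print(table(module = x$labels))
  invisible(x)
}

#' Choose the number of modules by BIC
#'
#' Fits L = 1..L_max and returns the assignment minimizing
#' BIC = -2 loglik + (4L - 1) log(nm); the full BIC path is attached.
#'
#' @inheritParams functional_cluster
#' @param L_max largest module count tried
#' @return the best `"module_assignment"`, with a `bic_path` element
#' @export
select_L <- function(M, L_max = 6, seed = 1, n_starts = 3, tol = 1e-6,
                     max_iter = 200) {
  fits <- lapply(seq_len(L_max), function(L)
    tryCatch(functional_cluster(M, L, seed = seed, n_starts = n_starts,
                                tol = tol, max_iter = max_iter),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("functional clustering failed for every L")
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 0)
  best <- fits[[which.min(replace(bics, !ok, Inf))]]
  best$bic_path <- data.frame(L = seq_len(L_max), bic = bics)
  best
}

#' Module-mean abundance profiles
#'
#' Column l is the per-sample arithmetic mean abundance of the taxa
#' assigned to module l; these coarse profiles drive the module-level
#' (coarse-grained) network.
#'
#' @param M an `abund` object
#' @param assignment a `"module_assignment"` covering all taxa of `M`
#' @param agg `"mean"` (default) or `"sum"`
#' @return an `abund` object, samples x L
#' @export
module_profiles <- function(M, assignment, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  lab <- assignment$labels[taxa(M)]
  if (anyNA(lab)) stop("assignment does not cover all taxa")
  mods <- sort(unique(lab))
  prof <- vapply(mods, function(l) {
    cols <- M$values[, lab == l, drop = FALSE]
    if (agg == "mean") rowMeans(cols) else rowSums(cols)
  }, numeric(nrow(M$values)))
  colnames(prof) <- sprintf("module%d", mods)
  abundance_matrix(prof, context = M$context, position = M$position,
                   subject = M$subject, drop_empty = FALSE)
}

#' Recursively split large modules
#'
#' Applies [functional_cluster()] within any module larger than
#' `max_size`, relabeling until every module is tractable.
#'
#' @param M an `abund` object
#' @param assignment an initial `"module_assignment"`
#' @param max_size split threshold (default 15 taxa)
#' @param L_max largest submodule count tried per split
#' @param seed RNG seed
#' @return named integer vector of refined labels
#' @export
refine_modules <- function(M, assignment, max_size = 15, L_max = 4,
                           seed = 1) {
  labels <- assignment$labels[taxa(M)]
  repeat {
    sizes <- table(labels)
    big <- names(sizes)[sizes > max_size]
    if (!length(big)) break
    l <- big[1]
    members <- names(labels)[labels == as.integer(l)]
    sub <- select_L(M[, members], L_max = min(L_max, length(members)),
                    seed = seed)
    if (sub$L == 1) break                      # cannot split further
    new_base <- max(labels)
    labels[members] <- ifelse(sub$labels == 1, labels[members][1],
                              new_base + sub$labels - 1L)
  }
  labels
}
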