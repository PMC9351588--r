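# Quasi-dynamic ODE stage: each taxon's abundance is decomposed along the
# habitat-index axis into an independent component G_j (its own capacity)
# and one dependent component G_jj' per selected partner, with
#   dG_j/dH  = Q_j(.)      and      dG_jj'/dH = Q_jj'(y_j'(H)),
# Q functions expanded in Legendre polynomials of log abundance mapped to
# [-1, 1], carrying the allometric per-capita prefactor yhat_j(H)/H.
# Because the argument curves are fixed functions of H, every trajectory
# is linear in the LOP coefficients: the design columns are cumulative
# RK4 integrals of the basis functions, and each component fit is an
# exact weighted least squares.

# Cumulative RK4 integration of a vector-valued, state-independent RHS
# along 'grid'; nsub substeps per grid interval. Returns length(grid) x p.
.cum_rk4 <- function(eval_fn, grid, nsub = 8) {
  n <- length(grid)
  ni <- n - 1L
  if (ni == 0L) return(matrix(0, 1, ncol(eval_fn(grid[1]))))
  hstep <- diff(grid) / nsub                      # per-interval substep
  s_off <- (seq_len(nsub) - 1L)
  t0 <- rep(grid[-n], nsub) + rep(hstep, nsub) * rep(s_off, each = ni)
  hh <- rep(hstep, nsub)
  E0 <- eval_fn(t0)
  Em <- eval_fn(t0 + hh / 2)
  E1 <- eval_fn(t0 + hh)
  contrib <- (hh / 6) * (E0 + 4 * Em + E1)        # RK4 increment, f(H) only
  inc <- rowsum(contrib, group = rep(seq_len(ni), nsub))
  rbind(0, apply(inc, 2, cumsum))
}

# Strictly increasing habitat grid: duplicated values perturbed upward by
# 1e-12 * range with a warning (the ODE needs a strictly increasing axis).
.strict_grid <- function(H) {
  if (anyDuplicated(H)) {
    warning("duplicate habitat indices perturbed by 1e-12 * range")
    eps <- 1e-12 * diff(range(H))
    if (eps == 0) eps <- 1e-12
    while (anyDuplicated(H)) {
      d <- duplicated(H)
      H[d] <- H[d] + eps
    }
    H <- sort(H)
  }
  H
}

# Precompute, for one focal taxon, the full-grid cumulative design matrix.
# Column blocks: [self (r+1)] then one (r+1) block per selected partner.
# The self Q argument is the focal's smoothed power curve; partner Q
# arguments default to the partners' observed abundances, interpolated
# piecewise-linearly along the habitat axis (each partner's realized curve
# carries its own variation, which is what identifies the attribution).
.qdode_design_taxon <- function(focal, partners, fits, grid, order, nsub,
                                Y = NULL, predictor = "observed") {
  curve_fn <- function(tx) {
    if (predictor == "smoothed" || tx == focal || is.null(Y)) {
      f <- fits[[tx]]
      mp <- map_log_unit(smoothed_abundance(f, grid))
      list(fn = function(h) predict(f, h), mp = mp)
    } else {
      yo <- Y[, tx]
      list(fn = stats::approxfun(grid, yo, rule = 2), mp = map_log_unit(yo))
    }
  }
  curves <- lapply(c(focal, partners), curve_fn)
  names(curves) <- c(focal, partners)
  ffit <- fits[[focal]]
  eval_fn <- function(h) {
    # allometric per-capita scaling: every derivative term carries the
    # prefactor yhat_j(H)/H, so that a pure power law (dy/dH = beta y/H)
    # corresponds to a constant Q and trajectories track the focal's
    # dynamic range exactly
    pref <- predict(ffit, h) / h
    do.call(cbind, lapply(curves, function(cv) {
      x <- log(pmax(cv$fn(h), cv$mp$floor))
      u <- if (cv$mp$hi - cv$mp$lo > 0) map_unit(x, cv$mp$lo, cv$mp$hi)
           else rep(0, length(x))
      pref * legendre_basis(u, order)
    }))
  }
  F <- .cum_rk4(eval_fn, grid, nsub)
  idx <- split(seq_len((order + 1) * (1 + length(partners))),
               rep(seq_len(1 + length(partners)), each = order + 1))
  names(idx) <- c(focal, partners)
  list(F = F, cols = idx)
}

# Pointwise component estimates on the log scale: the focal's log
# abundance is regressed on its own (smoothed, order + 2) block plus one
# block per selected partner; the fitted per-partner terms are the
# identifiable attribution (they ride on each partner's individual
# variation), which the ODE stage then projects onto smooth trajectories.
.pointwise_components <- function(yo, yhat, partnersY, order) {
  pos <- yo[yo > 0]
  ly <- log(pmax(yo, 0.5 * min(pos)))
  blk <- function(x, ord_b) {
    mp <- map_log_unit(x)
    if (mp$hi - mp$lo <= 0) return(matrix(1, length(x), 1))
    legendre_basis(mp$u, ord_b)
  }
  self <- blk(yhat, order + 2)
  mps <- lapply(partnersY, map_log_unit)
  pb_raw <- lapply(partnersY, function(x) blk(x, order))
  # project the smooth (habitat-driven) span of the self block out of
  # every partner block: the attribution of anything expressible by the
  # focal's own curve family belongs to the independent component, and
  # partner terms keep only the partner-specific (identifiable) variation
  qs <- qr(self)
  pb <- lapply(pb_raw, function(B) {
    cf <- qr.coef(qs, B)
    cf[is.na(cf)] <- 0
    B - self %*% cf
  })
  A <- do.call(cbind, c(list(self), pb))
  cf <- .wls(A, ly, rep(1, length(ly)))
  k0 <- ncol(self)
  a_part <- drop(self %*% cf[seq_len(k0)])
  # direction of influence: slope of the full (raw-basis) response fit,
  # ridge-stabilized along the degenerate shared-trend direction
  cf_raw <- .wls_ridge(do.call(cbind, c(list(self), pb_raw)), ly,
                       rep(1, length(ly)), lambda_rel = 1e-3)
  off <- k0
  slopes <- numeric(length(pb))
  shares <- vapply(seq_along(pb), function(g) {
    nc <- ncol(pb[[g]])
    th <- cf[off + seq_len(nc)]
    th_raw <- cf_raw[off + seq_len(nc)]
    if (nc > 1)
      slopes[g] <<- mean(drop(legendre_deriv(mps[[g]]$u, nc - 1) %*% th_raw))
    out <- drop(pb[[g]] %*% th)
    off <<- off + nc
    out
  }, numeric(length(ly)))
  if (!length(pb)) shares <- matrix(0, length(ly), 0)
  list(indep = exp(a_part), shares = shares, slopes = slopes)
}

# Ridge-stabilized weighted least squares for the trajectory projections:
# integral columns of nearby basis functions are nearly collinear, and an
# unstabilized solve can run away at the weakly weighted boundary.
.wls_ridge <- function(A, y, z, lambda_rel = 1e-6) {
  Aw <- A * z
  G <- crossprod(Aw, A)
  lam <- lambda_rel * mean(diag(G))
  cf <- tryCatch(solve(G + diag(lam, ncol(A)), crossprod(Aw, y)),
                 error = function(e) NULL)
  if (is.null(cf)) return(.wls(A, y, z))
  drop(cf)
}

# Split the original-scale dependent total across partners in proportion
# to their (signed) log-scale shares.
.split_components <- function(indep, shares) {
  if (!ncol(shares)) return(shares)
  dep_tot <- indep * (exp(rowSums(shares)) - 1)
  tot <- rowSums(abs(shares))
  (shares / ifelse(tot > 0, tot, 1)) * abs(dep_tot)
}

# Closed-form weighted least-squares fit of the component coefficients on a
# (subset of the) grid. idx must be increasing sample positions.
.qdode_solve <- function(F, cols, y, grid, idx = seq_along(y),
                         weights = "parabolic", wscale = NULL) {
  Fs <- sweep(F[idx, , drop = FALSE], 2, F[idx[1], ])
  gs <- grid[idx]
  ys <- y[idx]
  z <- convergence_weights(gs, weights,
                           scale = if (!is.null(wscale)) wscale[idx])
  theta <- .wls(Fs, ys - ys[1], z)
  comp <- lapply(cols, function(cc) drop(Fs[, cc, drop = FALSE] %*% theta[cc]))
  comp[[1]] <- comp[[1]] + ys[1]            # independent carries y(H_(1))
  fitted <- Reduce(`+`, comp)
  list(theta = theta, components = comp, fitted = fitted, z = z,
       grid = gs, observed = ys,
       rss = sum(z * (ys - fitted)^2),
       sigma2 = sum((ys - fitted)^2) / length(ys))
}

#' Fit the sparse quasi-dynamic ODE system
#'
#' For each focal taxon, parameterizes the independent derivative Q_j as
#' an LOP series in the focal's smoothed abundance and each dependent
#' derivative Q_jj' as an LOP series in the selected partner's abundance
#' (all with the allometric per-capita prefactor yhat_j(H)/H), and
#' integrates the component system along the sorted habitat-index grid by
#' RK4. Estimation is two-step: a pointwise log-scale regression of the
#' focal on its own smoothed block plus the selected partners fixes the
#' attribution of abundance to components (the attribution is identified
#' by each partner's individual variation); each component trajectory is
#' then the exact weighted-least-squares projection of its pointwise
#' target onto its own Q-integral block, so trajectories remain RK4
#' integrals of their own Q terms and the decomposition is additive to
#' machine precision. At the smallest habitat index the observed
#' abundance is assigned wholly to the independent component and every
#' dependent component starts at 0.
#'
#' @param M an `abund` object
#' @param links a [select_links()] result (or named list whose element
#'   `$selected` gives each focal taxon's partners)
#' @param order LOP degree for the Q functions (default 3)
#' @param fits optional [fit_power_all()] result
#' @param predictor Q-argument choice for partner terms: `"observed"`
#'   (default; partner's realized abundance interpolated along the habitat
#'   axis) or `"smoothed"` (its power-fit curve). The focal's own Q always
#'   takes its smoothed curve.
#' @param weights `"parabolic"` or `"none"` (see [build_design()])
#' @param nsub RK4 substeps per grid interval (default 8)
#' @return object of class `"qdode_fit_list"`: one `"qdode_fit"` per taxon
#'   with fields `theta_self`, `theta_partner`, `grid`, `independent_traj`,
#'   `dependent_traj`, `fitted`, `observed`, `sigma2`, `rss`, `converged`.
#' @export
fit_qdode <- function(M, links, order = 3, fits = NULL,
                      predictor = c("observed", "smoothed"),
                      weights = c("parabolic", "none"), nsub = 8) {
  predictor <- match.arg(predictor)
  weights <- match.arg(weights)
  stopifnot(inherits(M, "abund"))
  if (is.null(fits)) fits <- fit_power_all(M)
  H <- habitat_index(M)
  ord <- order(H)
  grid <- .strict_grid(H[ord])
  Y <- M$values[ord, , drop = FALSE]
  out <- lapply(taxa(M), function(tx) {
    partners <- intersect(links[[tx]]$selected, taxa(M))
    des <- .qdode_design_taxon(tx, partners, fits, grid, order, nsub,
                               Y = Y, predictor = predictor)
    y <- M$values[ord, tx]
    yhat <- smoothed_abundance(fits[[tx]], grid)
    z <- convergence_weights(grid, weights)
    Fs <- sweep(des$F, 2, des$F[1, ])
    # two-step estimation: the pointwise log-scale regression fixes the
    # attribution of abundance to partners (the integral design alone is
    # degenerate across smooth components); each component trajectory is
    # then the projection of its pointwise target onto its own Q-integral
    # block
    pw <- .pointwise_components(y, yhat, lapply(partners, function(p)
      Y[, p]), order)
    dep_targets <- .split_components(pw$indep, pw$shares)
    theta <- numeric(ncol(Fs))
    dep_traj <- vector("list", length(partners))
    names(dep_traj) <- partners
    for (g in seq_along(partners)) {
      cc <- des$cols[[g + 1]]
      theta[cc] <- .wls_ridge(Fs[, cc, drop = FALSE], dep_targets[, g], z)
      dep_traj[[g]] <- drop(Fs[, cc, drop = FALSE] %*% theta[cc])
    }
    names(pw$slopes) <- partners
    dep_sum <- if (length(partners)) Reduce(`+`, dep_traj) else 0
    cc1 <- des$cols[[1]]
    theta[cc1] <- .wls_ridge(Fs[, cc1, drop = FALSE], y - y[1] - dep_sum, z)
    indep <- y[1] + drop(Fs[, cc1, drop = FALSE] %*% theta[cc1])
    fitted <- indep + dep_sum
    if (!all(is.finite(fitted)))
      stop(sprintf("non-finite qdODE trajectory for taxon '%s'", tx))
    structure(list(focal = tx,
                   theta_self = theta[cc1],
                   theta_partner = lapply(des$cols[-1], function(cc)
                     theta[cc]),
                   grid = grid,
                   sample_ids = samples(M)[ord],
                   independent_traj = indep,
                   dependent_traj = dep_traj,
                   partner_slopes = pw$slopes,
                   fitted = fitted, observed = y,
                   z = z, rss = sum(z * (y - fitted)^2),
                   sigma2 = sum((y - fitted)^2) / length(y),
                   converged = TRUE),
              class = "qdode_fit")
  })
  names(out) <- taxa(M)
  structure(out, perm = ord, class = "qdode_fit_list")
}

#' @export
print.qdode_fit <- function(x, ...) {
  cat(sprintf("qdODE fit for '%s': %d partner(s), sigma2 = %.4g\n",
              x$focal, length(x$dependent_traj), x$sigma2))
  invisible(x)
}

#' @export
print.qdode_fit_list <- function(x, ...) {
  cat(sprintf("qdODE fits for %d taxa; mean sigma2 = %.4g\n", length(x),
              mean(vapply(x, function(f) f$sigma2, 0))))
  invisible(x)
}

#' Decompose a fitted taxon into per-sample components
#'
#' Per sample: the independent component, each partner's dependent
#' component, and the positive (promotion) and negative (inhibition)
#' dependent totals. Subject- or position-level summaries are means of
#' these columns over the relevant sample subset.
#'
#' @param fit a `"qdode_fit"`
#' @return data.frame with columns `sample`, `H`, `observed`, `fitted`,
#'   `independent`, `dependent_pos`, `dependent_neg`, then one column per
#'   partner.
#' @export
decompose <- function(fit) {
  stopifnot(inherits(fit, "qdode_fit"), isTRUE(fit$converged))
  dep <- if (length(fit$dependent_traj))
    do.call(cbind, fit$dependent_traj)
  else matrix(0, length(fit$grid), 0)
  pos <- if (ncol(dep)) rowSums(pmax(dep, 0)) else rep(0, length(fit$grid))
  neg <- if (ncol(dep)) rowSums(pmin(dep, 0)) else rep(0, length(fit$grid))
  out <- data.frame(sample = fit$sample_ids, H = fit$grid,
                    observed = fit$observed, fitted = fit$fitted,
                    independent = fit$independent_traj,
                    dependent_pos = pos, dependent_neg = neg,
                    stringsAsFactors = FALSE)
  if (ncol(dep)) out <- cbind(out, dep)
  rownames(out) <- NULL
  out
}

#' Residual covariance model across taxa
#'
#' Estimates the per-taxon residual variances and pairwise residual
#' covariances from the qdODE residuals; the implied full covariance is
#' block-structured with sigma_{j1 j2} I_n off-diagonal blocks.
#'
#' @param fits a `"qdode_fit_list"`
#' @return class `"qdode_cov"`: list with the m x m residual covariance
#'   `sigma` and the sample count `n`
#' @export
residual_covariance <- function(fits) {
  R <- vapply(fits, function(f) f$observed - f$fitted,
              numeric(length(fits[[1]]$observed)))
  S <- crossprod(R) / nrow(R)
  structure(list(sigma = S, n = nrow(R)), class = "qdode_cov")
}

# Shrink off-diagonal entries toward 0 by the smallest power of 0.95
# restoring positive-definiteness.
.make_pd <- function(S) {
  k <- 0
  D <- diag(diag(S), nrow(S))
  while (k < 200) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-12 * max(abs(ev), 1)) break
    S <- D + (S - D) * 0.95
    k <- k + 1
  }
  if (k > 0) warning(sprintf("covariance off-diagonals shrunk by 0.95^%d for positive-definiteness", k))
  S
}

#' Gaussian log-likelihood of the qdODE residuals
#'
#' Joint normal log-likelihood of all taxa's residual vectors under the
#' block covariance with sigma_{j1 j2} I_n off-diagonal blocks (so the full
#' nm x nm covariance is S (x) I_n for the m x m residual covariance S).
#'
#' @param fits a `"qdode_fit_list"` (all on the same sample grid)
#' @param cov a `"qdode_cov"`, an m x m covariance matrix, or `NULL` to
#'   estimate from the residuals
#' @return log-likelihood (numeric scalar)
#' @export
qdode_loglik <- function(fits, cov = NULL) {
  R <- vapply(fits, function(f) f$observed - f$fitted,
              numeric(length(fits[[1]]$observed)))
  n <- nrow(R); m <- ncol(R)
  S <- if (is.null(cov)) crossprod(R) / n
       else if (inherits(cov, "qdode_cov")) cov$sigma
       else cov
  S <- .make_pd(S)
  ch <- chol(S)
  logdet <- 2 * sum(log(diag(ch)))
  Si <- chol2inv(ch)
  quad <- sum((R %*% Si) * R)
  -(n * m / 2) * log(2 * pi) - (n / 2) * logdet - quad / 2
}
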