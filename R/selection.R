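#' Build the group-penalized regression design for one focal taxon
#'
#' The focal taxon's log abundance (response) is regressed, across samples
#' sorted by habitat index W, on one Legendre-polynomial block per partner
#' taxon. Abundance data are lognormal-heteroscedastic and span orders of
#' magnitude, so estimation is carried out on the log scale, where the
#' noise is homoscedastic and power-law structure is linear; the selected
#' support is what feeds the (original-scale) ODE stage. Each partner
#' enters through its observed abundance (default) or its power-fit
#' smoothed curve, log-transformed and affinely mapped to \[-1, 1\]; an
#' unpenalized block in the focal's own *smoothed* abundance represents
#' the independent component a_j(W) (the focal's own observed values are
#' never used as its own predictor, which would fit noise pointwise). A
#' prescribed non-negative weight vector z with z(W_1) = z(W_n) = 0
#' down-weights the boundary samples.
#'
#' @param M an `abund` object
#' @param focal focal taxon id
#' @param order Legendre polynomial degree r (block width r + 1)
#' @param fits optional [fit_power_all()] result (computed when missing)
#' @param predictor `"observed"` (raw partner abundances, default) or
#'   `"smoothed"` (power-fit curves; note smoothed power curves of
#'   different taxa are near-collinear, which defeats partner
#'   identification — offered for smooth-data settings only)
#' @param weights `"parabolic"` (default) or `"none"`
#' @return list with response `y`, sorted habitat index `H`, weight vector
#'   `z`, unpenalized `self_block`, named list `blocks` of n x (r+1)
#'   partner design blocks, block scale factors, and the sample permutation
#'   applied.
#' @export
build_design <- function(M, focal, order = 3, fits = NULL,
                         predictor = c("observed", "smoothed"),
                         weights = c("parabolic", "none")) {
  predictor <- match.arg(predictor)
  weights <- match.arg(weights)
  stopifnot(inherits(M, "abund"), focal %in% taxa(M))
  if (is.null(fits)) fits <- fit_power_all(M)
  H <- habitat_index(M)
  ord <- order(H)
  H <- H[ord]
  yo <- M$values[ord, focal]
  pos <- yo[yo > 0]
  if (!length(pos)) stop(sprintf("taxon '%s' has no positive abundance", focal))
  y <- log(pmax(yo, 0.5 * min(pos)))
  z <- convergence_weights(H, weights)
  block_for <- function(tx, ord_b) {
    x <- if (predictor == "smoothed" || tx == focal)
           smoothed_abundance(fits[[tx]], H)
         else M$values[ord, tx]
    mp <- map_log_unit(x)
    if (mp$hi - mp$lo <= 0)
      return(structure(matrix(1, length(H), 1,
                              dimnames = list(NULL, "P0")), constant = TRUE))
    legendre_basis(mp$u, ord_b)
  }
  partners <- setdiff(taxa(M), focal)
  blocks <- lapply(partners, function(tx) block_for(tx, order))
  names(blocks) <- partners
  # unit Frobenius norm per penalized block, so the group penalty treats
  # partners on a common scale; coefficients are back-transformed on return
  scales <- vapply(blocks, function(B) sqrt(sum(B^2)), 0)
  blocks <- Map(function(B, s) B / s, blocks, scales)
  # the unpenalized independent block gets two extra degrees: it must be
  # able to absorb any habitat-driven curvature, or partner blocks (whose
  # arguments are near-monotone in H) would soak it up as spurious links
  list(focal = focal, y = y, H = H, z = z,
       self_block = block_for(focal, order + 2),
       blocks = blocks, scales = scales, order = order,
       constant = vapply(blocks, function(B) isTRUE(attr(B, "constant")), TRUE),
       perm = ord)
}

# Weighted least squares of y on A with weights z (zeros allowed);
# rank-deficient columns get coefficient 0.
.wls <- function(A, y, z) {
  f <- stats::lm.wfit(A, y, w = z)
  cf <- f$coefficients
  cf[is.na(cf)] <- 0
  cf
}

# Per-design precomputation shared across the whole lambda path: stacked
# design, block index bounds, and the self block's weighted pseudo-inverse
# (its unpenalized update is then a matrix-vector product).
.gl_precompute <- function(design) {
  z <- design$z
  blocks <- design$blocks
  Xs <- design$self_block
  sz <- sqrt(z)
  qrs <- qr(Xs * sz)
  keep <- qrs$pivot[seq_len(qrs$rank)]
  R <- qr.R(qrs)[seq_len(qrs$rank), seq_len(qrs$rank), drop = FALSE]
  # pseudo-inverse restricted to the identifiable columns
  pinv <- matrix(0, ncol(Xs), length(z))
  pinv[keep, ] <- backsolve(R, backsolve(R, t(Xs[, keep, drop = FALSE] * z),
                                         transpose = TRUE))
  sizes <- vapply(blocks, ncol, 0L)
  list(X = do.call(cbind, blocks),
       gstart = c(0L, cumsum(sizes))[seq_along(sizes)],  # 0-based
       gsize = sizes,
       self_pinv = pinv)
}

# Block-coordinate descent for the group-penalized weighted least-squares
# criterion
#   (y - a - sum_g X_g b_g)' Z (y - a - sum_g X_g b_g)
#     + lambda * sum_g w_g ||b_g||_2
# with the intercept (self) block unpenalized; compiled exact-block solver.
.bcd_group_lasso <- function(y, self_block, blocks, z, lambda, w = NULL,
                             beta = NULL, max_iter = 1000, tol = 1e-7,
                             pre = NULL) {
  G <- length(blocks)
  if (is.null(w)) w <- rep(1, G)
  if (is.null(beta)) beta <- lapply(blocks, function(B) numeric(ncol(B)))
  if (is.null(pre))
    pre <- .gl_precompute(list(z = z, blocks = blocks, self_block = self_block))
  out <- .bcd_cpp(y, self_block, pre$X, as.integer(pre$gstart),
                  as.integer(pre$gsize), z, lambda, w, unlist(beta),
                  pre$self_pinv, as.integer(max_iter), tol)
  bounds <- c(0L, cumsum(pre$gsize))
  beta_list <- lapply(seq_len(G), function(g)
    out$beta[(bounds[g] + 1L):bounds[g + 1L]])
  names(beta_list) <- names(blocks)
  list(a = drop(out$a), beta = beta_list, residual = drop(out$residual),
       objective = out$objective, iterations = out$iterations,
       converged = out$converged)
}

# Group-lasso degrees of freedom (Yuan & Lin style): for each active group,
# 1 + order * ||b_g|| / ||b_g^marginal-OLS||.
.gl_df <- function(beta, ols_norms, order) {
  nb <- vapply(beta, function(b) sqrt(sum(b^2)), 0)
  act <- nb > 0
  if (!any(act)) return(0)
  ratio <- pmin(nb[act] / pmax(ols_norms[act], 1e-12), 1)
  sum(1 + order * ratio)
}

#' Stage-1 group LASSO partner selection for one focal taxon
#'
#' Minimizes the penalized weighted least-squares criterion over a
#' descending lambda path by block-coordinate proximal descent with warm
#' starts, and picks the path point minimizing BIC (or extended BIC).
#'
#' @param design a [build_design()] result
#' @param lambda optional decreasing penalty grid; default 50 log-spaced
#'   values from lambda_max down to 0.001 lambda_max
#' @param nlambda,lambda_min_ratio grid size and lower end (as a fraction
#'   of lambda_max) when `lambda` is not given
#' @param criterion `"BIC"` or `"eBIC"`
#' @param ebic_gamma extended-BIC gamma (default 0.5)
#' @param max_iter,tol solver controls
#' @return object of class `"link_selection"`: selected partner ids,
#'   back-transformed per-partner coefficient groups, chosen `lambda`, the
#'   full `path` (lambda, criterion value, active-set size), and the
#'   adaptive weights implied by the fit.
#' @export
group_lasso <- function(design, lambda = NULL, nlambda = 50,
                        lambda_min_ratio = 1e-5,
                        criterion = c("BIC", "eBIC"), ebic_gamma = 0.5,
                        max_iter = 1000, tol = 1e-7) {
  criterion <- match.arg(criterion)
  y <- design$y; z <- design$z; blocks <- design$blocks
  n <- length(y); G <- length(blocks)
  a0 <- .wls(design$self_block, y, z)
  r0 <- y - drop(design$self_block %*% a0)
  score0 <- vapply(blocks, function(B) 2 * sqrt(sum((drop(t(B * z) %*% r0))^2)), 0)
  lambda_max <- max(score0, 1e-12)
  if (is.null(lambda))
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  lambda <- sort(lambda, decreasing = TRUE)
  ols_norms <- vapply(blocks, function(B)
    sqrt(sum(.wls(B, r0, z)^2)), 0)
  pre <- .gl_precompute(design)
  beta <- NULL
  path <- data.frame(lambda = lambda, crit = NA_real_, df = NA_real_,
                     active = NA_integer_, rss = NA_real_,
                     converged = NA)
  sols <- vector("list", length(lambda))
  dfmax <- max(2, floor(0.9 * n / (design$order + 1)))
  for (k in seq_along(lambda)) {
    sol <- .bcd_group_lasso(y, design$self_block, blocks, z, lambda[k],
                            beta = beta, max_iter = max_iter, tol = tol,
                            pre = pre)
    beta <- sol$beta
    rss <- sum(z * sol$residual^2)
    act_g <- vapply(sol$beta, function(b) any(b != 0), TRUE)
    act <- sum(act_g)
    # score the support on the debiased (refitted) scale, the same scale on
    # which an exhaustive subset search would score it; the path solution
    # itself is only used to determine the support
    A <- do.call(cbind, c(list(design$self_block), blocks[act_g]))
    rfit <- stats::lm.wfit(A, y, z)
    rss_refit <- sum(z * rfit$residuals^2)
    df <- sum(vapply(blocks[act_g], ncol, 0L))
    crit <- n * log(max(rss_refit, 1e-300) / n) + df * log(n)
    if (criterion == "eBIC")
      crit <- crit + 2 * ebic_gamma * lchoose(G, act)
    path[k, c("crit", "df", "active", "rss")] <- c(crit, df, act, rss)
    path$converged[k] <- sol$converged
    sols[[k]] <- sol
    if (act > dfmax) break   # saturated; smaller lambdas are not candidates
  }
  ok <- which(path$converged & !vapply(sols, is.null, TRUE))
  if (!length(ok)) stop("group lasso failed to converge at every lambda")
  best <- ok[which.min(path$crit[ok])]
  res <- .selection_result(design, sols[[best]], lambda[best], path,
                           stage = "group")
  # screening norms: a group's largest norm anywhere on the converged
  # path; groups that never enter the path stay excluded downstream
  res$screen_norms <- apply(vapply(sols[ok], function(sol)
    vapply(sol$beta, function(b) sqrt(sum(b^2)), 0),
    numeric(length(design$blocks))), 1, max)
  res
}

.selection_result <- function(design, sol, lambda, path, stage,
                              weights = NULL) {
  nb <- vapply(sol$beta, function(b) sqrt(sum(b^2)), 0)
  sel <- names(design$blocks)[nb > 0]
  sel <- sel[order(-nb[nb > 0])]
  beta_bt <- Map(function(b, s) b / s, sol$beta, design$scales)
  structure(list(focal = design$focal, selected = sel,
                 beta_groups = beta_bt[sel],
                 beta_std = sol$beta, group_norms = nb,
                 a_coef = sol$a, lambda = lambda, path = path,
                 weights = weights, stage = stage,
                 order = design$order, residual = sol$residual),
            class = "link_selection")
}

#' @export
print.link_selection <- function(x, ...) {
  cat(sprintf("Partner selection for '%s' (%s stage): %d partner(s)\n",
              x$focal, x$stage, length(x$selected)))
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Stage-2 adaptive group LASSO
#'
#' Re-solves the group-penalized criterion with per-group weights
#' w = 1 / ||b_g||_2 from the stage-1 estimates (each group's largest norm
#' along the stage-1 path, so stage 1 acts as a screener); groups that
#' never enter the stage-1 path carry infinite weight and stay excluded,
#' matching the w = Inf convention. An empty stage-1 selection is returned
#' as-is without a solver call.
#'
#' @param design a [build_design()] result
#' @param stage1 the stage-1 [group_lasso()] result
#' @inheritParams group_lasso
#' @param max_links optional hard ceiling on the number of partners kept
#'   (largest group norms first)
#' @return final `"link_selection"`
#' @export
adaptive_group_lasso <- function(design, stage1, lambda = NULL, nlambda = 50,
                                 lambda_min_ratio = 1e-5,
                                 criterion = c("BIC", "eBIC"),
                                 ebic_gamma = 0.5, max_iter = 1000,
                                 tol = 1e-7, max_links = NULL) {
  criterion <- match.arg(criterion)
  nb <- stage1$screen_norms %||% stage1$group_norms
  if (!any(nb > 0)) {
    out <- stage1; out$stage <- "adaptive"
    out$weights <- rep(Inf, length(nb))
    return(out)
  }
  w <- ifelse(nb > 0, 1 / nb, Inf)
  w[is.finite(w)] <- w[is.finite(w)] / min(w[is.finite(w)])  # scale-free
  y <- design$y; z <- design$z; blocks <- design$blocks
  n <- length(y); G <- length(blocks)
  a0 <- .wls(design$self_block, y, z)
  r0 <- y - drop(design$self_block %*% a0)
  if (is.null(lambda)) {
    sc <- vapply(seq_along(blocks), function(g) {
      if (is.infinite(w[g])) return(0)
      2 * sqrt(sum((drop(t(blocks[[g]] * z) %*% r0))^2)) / w[g]
    }, 0)
    lmax <- max(sc, 1e-12)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  ols_norms <- vapply(blocks, function(B) sqrt(sum(.wls(B, r0, z)^2)), 0)
  pre <- .gl_precompute(design)
  beta <- NULL
  path <- data.frame(lambda = lambda, crit = NA_real_, df = NA_real_,
                     active = NA_integer_, rss = NA_real_, converged = NA)
  sols <- vector("list", length(lambda))
  dfmax <- max(2, floor(0.9 * n / (design$order + 1)))
  for (k in seq_along(lambda)) {
    sol <- .bcd_group_lasso(y, design$self_block, blocks, z, lambda[k],
                            w = w, beta = beta, max_iter = max_iter,
                            tol = tol, pre = pre)
    beta <- sol$beta
    rss <- sum(z * sol$residual^2)
    act_g <- vapply(sol$beta, function(b) any(b != 0), TRUE)
    act <- sum(act_g)
    # score the support on the debiased (refitted) scale, the same scale on
    # which an exhaustive subset search would score it; the path solution
    # itself is only used to determine the support
    A <- do.call(cbind, c(list(design$self_block), blocks[act_g]))
    rfit <- stats::lm.wfit(A, y, z)
    rss_refit <- sum(z * rfit$residuals^2)
    df <- sum(vapply(blocks[act_g], ncol, 0L))
    crit <- n * log(max(rss_refit, 1e-300) / n) + df * log(n)
    if (criterion == "eBIC")
      crit <- crit + 2 * ebic_gamma * lchoose(G, act)
    path[k, c("crit", "df", "active", "rss")] <- c(crit, df, act, rss)
    path$converged[k] <- sol$converged
    sols[[k]] <- sol
    if (act > dfmax) break   # saturated; smaller lambdas are not candidates
  }
  ok <- which(path$converged & !vapply(sols, is.null, TRUE))
  if (!length(ok)) stop("adaptive group lasso failed to converge")
  best <- ok[which.min(path$crit[ok])]
  res <- .selection_result(design, sols[[best]], lambda[best], path,
                           stage = "adaptive", weights = w)
  if (!is.null(max_links) && length(res$selected) > max_links)
    res$selected <- res$selected[seq_len(max_links)]
  res$beta_groups <- res$beta_groups[res$selected]
  res
}

#' Select interaction partners for every taxon
#'
#' Runs the two-stage (group LASSO, then adaptive group LASSO) selection
#' for each focal taxon in turn, sharing the power fits.
#'
#' @inheritParams build_design
#' @inheritParams group_lasso
#' @param max_links optional ceiling on partners per focal taxon
#' @return named list of final `"link_selection"` objects (class
#'   `"link_selection_list"`)
#' @export
select_links <- function(M, order = 3, fits = NULL,
                         predictor = c("observed", "smoothed"),
                         weights = c("parabolic", "none"),
                         nlambda = 50, criterion = c("BIC", "eBIC"),
                         ebic_gamma = 0.5, max_links = NULL,
                         max_iter = 1000, tol = 1e-7) {
  predictor <- match.arg(predictor)
  weights <- match.arg(weights)
  criterion <- match.arg(criterion)
  if (is.null(fits)) fits <- fit_power_all(M)
  out <- lapply(taxa(M), function(tx) {
    d <- build_design(M, tx, order = order, fits = fits,
                      predictor = predictor, weights = weights)
    s1 <- group_lasso(d, nlambda = nlambda, criterion = criterion,
                      ebic_gamma = ebic_gamma, max_iter = max_iter, tol = tol)
    adaptive_group_lasso(d, s1, nlambda = nlambda, criterion = criterion,
                         ebic_gamma = ebic_gamma, max_iter = max_iter,
                         tol = tol, max_links = max_links)
  })
  names(out) <- taxa(M)
  structure(out, class = "link_selection_list")
}

#' @export
print.link_selection_list <- function(x, ...) {
  d <- vapply(x, function(s) length(s$selected), 0L)
  cat(sprintf("Partner selection for %d taxa; links per taxon: %s\n",
              length(x), paste(range(d), collapse = "-")))
  invisible(x)
}
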