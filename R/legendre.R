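#' Legendre orthogonal polynomial basis
#'
#' Evaluates P_0..P_order at points of \[-1, 1\] by the Bonnet recurrence.
#' Column k+1 is P_k; P_0 is the constant polynomial. Used as the
#' nonparametric basis for the independent/dependent component functions.
#'
#' @param u numeric vector in \[-1, 1\]
#' @param order maximum polynomial degree r >= 0
#' @return matrix `length(u) x (order + 1)`
#' @export
legendre_basis <- function(u, order) {
  stopifnot(order >= 0)
  n <- length(u)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- u
  if (order >= 2)
    for (k in 1:(order - 1))
      P[, k + 2] <- ((2 * k + 1) * u * P[, k + 1] - k * P[, k]) / (k + 1)
  colnames(P) <- paste0("P", 0:order)
  P
}

# Affine map of x onto [-1, 1] given the anchoring range [lo, hi].
# Degenerate range (hi == lo) maps everything to 0 (constant curve).
map_unit <- function(x, lo, hi) {
  if (hi - lo <= 0) return(rep(0, length(x)))
  2 * (x - lo) / (hi - lo) - 1
}

# Prescribed convergence weights on the sorted habitat axis:
# z(W) = (W - W_1)(W_n - W), zero at both boundaries, optionally divided
# by scale^2 (residual variance proportional to the squared mean under
# multiplicative noise), normalized to max 1.
convergence_weights <- function(W, type = c("parabolic", "none"),
                                scale = NULL) {
  type <- match.arg(type)
  z <- if (type == "none") rep(1, length(W))
       else (W - min(W)) * (max(W) - W)
  # variance ~ scale^2 (multiplicative noise); the ratio is clamped to
  # 100:1 so no part of the habitat axis is left effectively unconstrained
  if (!is.null(scale)) z <- z / pmax(scale, max(scale) / 10)^2
  if (max(z) > 0) z <- z / max(z)
  z
}

# Affine map of log-abundance onto [-1, 1]: abundances are heavy-tailed,
# so the nonparametric basis is anchored on the log scale. Non-positive
# values are floored at half the smallest positive value.
map_log_unit <- function(x, lo = NULL, hi = NULL) {
  pos <- x[x > 0]
  if (!length(pos)) return(list(u = rep(0, length(x)), lo = 0, hi = 0,
                                floor = 1))
  fl <- 0.5 * min(pos)
  xl <- log(pmax(x, fl))
  if (is.null(lo)) lo <- min(xl)
  if (is.null(hi)) hi <- max(xl)
  list(u = map_unit(xl, lo, hi), lo = lo, hi = hi, floor = fl)
}

# Derivatives P'_0..P'_order at points of [-1, 1], via the recurrence
# P'_k = (2k - 1) P_{k-1} + P'_{k-2}.
legendre_deriv <- function(u, order) {
  P <- legendre_basis(u, order)
  D <- matrix(0, length(u), order + 1)
  if (order >= 1) D[, 2] <- 1
  if (order >= 2)
    for (k in 2:order)
      D[, k + 1] <- (2 * k - 1) * P[, k] + if (k >= 2) D[, k - 1] else 0
  D
}
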