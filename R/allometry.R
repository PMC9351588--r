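#' Fit the allometric power law y = alpha * H^beta
#'
#' Links a taxon's niche index (its abundance y) to the habitat index H
#' (total sample abundance) by a power law. `method = "loglog"` is ordinary
#' least squares of log y on log H over the y > 0 samples (closed form,
#' the default); `method = "nls"` refines that solution by nonlinear least
#' squares on the original scale. Both R-squared conventions (log scale and
#' original scale) are always reported.
#'
#' @param y non-negative abundances of one taxon
#' @param H strictly positive habitat indices, same length
#' @param method `"loglog"` or `"nls"`
#' @param pseudocount added to y before fitting (default 0; zeros are
#'   dropped instead)
#' @return object of class `"power_fit"`: list with `alpha`, `beta`, `r2`
#'   (on the fitting scale), `r2_log`, `r2_original`, `scale`, `n_used`.
#' @examples
#' H <- exp(seq(log(10), log(1000), length.out = 30))
#' f <- fit_power(0.5 * H^1.2, H)
#' c(f$alpha, f$beta)
#' @export
fit_power <- function(y, H, method = c("loglog", "nls"), pseudocount = 0) {
  method <- match.arg(method)
  stopifnot(length(y) == length(H))
  if (any(H <= 0)) stop("habitat index must be strictly positive")
  y <- y + pseudocount
  pos <- y > 0
  if (sum(pos) < 3) stop("insufficient positive abundance")
  ly <- log(y[pos]); lh <- log(H[pos])
  # closed-form log-log OLS; degenerate (constant) cases handled explicitly
  vh <- stats::var(lh)
  if (vh == 0) stop("habitat index constant across samples; slope undefined")
  beta <- stats::cov(lh, ly) / vh
  a <- mean(ly) - beta * mean(lh)
  res <- ly - (a + beta * lh)
  tss <- sum((ly - mean(ly))^2)
  r2_log <- if (tss > 0) 1 - sum(res^2) / tss else 1
  alpha <- exp(a)
  if (method == "nls") {
    fitfun <- function(p) sum((y[pos] - exp(p[1]) * H[pos]^p[2])^2)
    nf <- tryCatch(
      minpack.lm::nlsLM(yy ~ exp(la) * hh^b,
                        data = list(yy = y[pos], hh = H[pos]),
                        start = list(la = a, b = beta),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nf) && fitfun(stats::coef(nf)) <= fitfun(c(a, beta))) {
      cf <- stats::coef(nf)
      alpha <- exp(cf[["la"]]); beta <- cf[["b"]]
    }
  }
  pred <- alpha * H[pos]^beta
  tss_o <- sum((y[pos] - mean(y[pos]))^2)
  r2_orig <- if (tss_o > 0) 1 - sum((y[pos] - pred)^2) / tss_o else 1
  structure(list(alpha = unname(alpha), beta = unname(beta),
                 r2 = if (method == "loglog") r2_log else r2_orig,
                 r2_log = r2_log, r2_original = r2_orig,
                 scale = if (method == "loglog") "log-log" else "original",
                 n_used = sum(pos)),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: y = %.4g * H^%.4g  (R2[%s] = %.3f, n = %d)\n",
              x$alpha, x$beta, x$scale, x$r2, x$n_used))
  invisible(x)
}

#' Evaluate a power-law fit at new habitat indices
#' @param object a `power_fit`
#' @param H strictly positive habitat indices
#' @param ... ignored
#' @return alpha * H^beta elementwise
#' @export
predict.power_fit <- function(object, H, ...) {
  if (any(H <= 0)) stop("habitat index must be strictly positive")
  object$alpha * H^object$beta
}

#' Fit the power law to every taxon of an abundance matrix
#'
#' Shares H = [habitat_index()] across taxa. Taxa with fewer than 3
#' positive observations receive a `NULL` fit and a warning rather than an
#' error.
#' @param M an `abund` object
#' @param method see [fit_power()]
#' @param pseudocount see [fit_power()]
#' @return object of class `"power_fit_list"`: named list of `power_fit`
#'   (or `NULL`), with the habitat index attached
#' @export
fit_power_all <- function(M, method = c("loglog", "nls"), pseudocount = 0) {
  method <- match.arg(method)
  H <- habitat_index(M)
  fits <- lapply(taxa(M), function(tx) {
    tryCatch(fit_power(M$values[, tx], H, method, pseudocount),
             error = function(e) {
               warning(sprintf("taxon '%s': %s", tx, conditionMessage(e)))
               NULL
             })
  })
  names(fits) <- taxa(M)
  structure(fits, H = H, class = "power_fit_list")
}

#' @export
print.power_fit_list <- function(x, ...) {
  cat(sprintf("Power-law fits for %d taxa (%d successful)\n",
              length(x), sum(!vapply(x, is.null, TRUE))))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.power_fit_list <- function(x, ...) {
  rows <- lapply(names(x), function(nm) {
    f <- x[[nm]]
    if (is.null(f))
      data.frame(taxon = nm, alpha = NA_real_, beta = NA_real_,
                 r2_log = NA_real_, r2_original = NA_real_, n_used = NA_integer_)
    else
      data.frame(taxon = nm, alpha = f$alpha, beta = f$beta,
                 r2_log = f$r2_log, r2_original = f$r2_original,
                 n_used = f$n_used)
  })
  do.call(rbind, rows)
}

# Smoothed abundance curve of one taxon evaluated at habitat indices H.
# The fitted power curve is the quasi-dynamic representation used by the
# selection and ODE stages.
smoothed_abundance <- function(fit, H) {
  if (is.null(fit)) stop("no power fit available for taxon")
  predict(fit, H)
}
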