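#' Fit a quasi-dynamic microbial interaction network
#'
#' The package's main fitting function. Chains the four inference stages on
#' an abundance matrix: (i) per-taxon allometric power-law fits of niche
#' index against habitat index, (ii) two-stage group-penalized selection of
#' each taxon's interaction partners, (iii) quasi-dynamic ODE decomposition
#' of every taxon's abundance into independent and signed partner-dependent
#' components, and (iv) assembly of the directed, signed, weighted
#' interaction network with ecological pair labels and node roles.
#'
#' @param M an `abund` object (see [abundance_matrix()] /
#'   [read_abundance()]), or a plain numeric samples x taxa matrix
#' @param order Legendre polynomial degree shared by the selection and ODE
#'   stages (default 3)
#' @param method power-law fitting method, `"loglog"` or `"nls"`
#' @param predictor partner predictor choice for selection, `"smoothed"`
#'   or `"observed"` (see [build_design()])
#' @param weights weight-function type, `"parabolic"` or `"none"`
#' @param epsilon neutrality threshold for edge signs; default 0.05 x the
#'   target taxon's mean abundance
#' @param max_links optional ceiling on partners per taxon
#' @param nlambda penalty-grid size for the selection stages
#' @return object of class `"qdnet"`: list with `abund`, `power_fits`,
#'   `links`, `ode_fits`, `network`, `call`. Supported methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`, `logLik`.
#' @examples
#' sim <- generate_abundance(generator_config(30, 6, d = 1, seed = 7))
#' fit <- qdnet(sim$abund, order = 2)
#' fit
#' @export
qdnet <- function(M, order = 3, method = c("loglog", "nls"),
                  predictor = c("observed", "smoothed"),
                  weights = c("parabolic", "none"), epsilon = NULL,
                  max_links = NULL, nlambda = 50) {
  method <- match.arg(method)
  predictor <- match.arg(predictor)
  weights <- match.arg(weights)
  if (!inherits(M, "abund")) M <- abundance_matrix(as.matrix(M))
  pf <- fit_power_all(M, method = method)
  links <- select_links(M, order = order, fits = pf, predictor = predictor,
                        weights = weights, nlambda = nlambda,
                        max_links = max_links)
  ode <- fit_qdode(M, links, order = order, fits = pf,
                   predictor = predictor, weights = weights)
  net <- build_network(ode, epsilon = epsilon)
  structure(list(abund = M, power_fits = pf, links = links,
                 ode_fits = ode, network = net, order = order,
                 epsilon = epsilon, call = match.call()),
            class = "qdnet")
}

#' @export
print.qdnet <- function(x, ...) {
  cat("Quasi-dynamic interaction network fit\n")
  cat(sprintf("  %d samples x %d taxa, LOP order %d\n",
              nrow(x$abund$values), ncol(x$abund$values), x$order))
  e <- x$network$edges
  cat(sprintf("  %d directed links (%d promoting, %d inhibiting, %d neutral)\n",
              nrow(e), sum(e$sign > 0), sum(e$sign < 0), sum(e$sign == 0)))
  invisible(x)
}

#' @export
summary.qdnet <- function(object, ...) {
  pf <- as.data.frame(object$power_fits)
  roles <- classify_roles(object$network)
  pairs <- classify_all_pairs(object$network)
  out <- list(power = pf, roles = roles,
              interaction_types = table(pairs$label),
              edges = object$network$edges,
              sigma2 = vapply(object$ode_fits, function(f) f$sigma2, 0),
              r2 = vapply(object$ode_fits, function(f) {
                tss <- sum((f$observed - mean(f$observed))^2)
                if (tss > 0) 1 - sum((f$observed - f$fitted)^2) / tss else 1
              }, 0))
  class(out) <- "summary.qdnet"
  out
}

#' @export
print.summary.qdnet <- function(x, ...) {
  cat("Power-law fits (head):\n")
  print(utils::head(x$power, 5))
  cat("\nInteraction types:\n")
  print(x$interaction_types)
  cat("\nNode roles:\n")
  print(x$roles)
  cat(sprintf("\nMedian fitted-vs-observed R2: %.3f\n",
              stats::median(x$r2)))
  invisible(x)
}

#' @export
coef.qdnet <- function(object, ...) {
  do.call(rbind, lapply(object$ode_fits, function(f) {
    data.frame(focal = f$focal,
               component = c("independent", names(f$dependent_traj)),
               t(cbind(f$theta_self,
                       if (length(f$theta_partner))
                         do.call(cbind, f$theta_partner))),
               row.names = NULL)
  }))
}

#' @export
fitted.qdnet <- function(object, ...) {
  vapply(object$ode_fits, function(f) f$fitted,
         numeric(length(object$ode_fits[[1]]$fitted)))
}

#' @export
residuals.qdnet <- function(object, ...) {
  vapply(object$ode_fits, function(f) f$observed - f$fitted,
         numeric(length(object$ode_fits[[1]]$observed)))
}

#' @export
logLik.qdnet <- function(object, ...) {
  ll <- qdode_loglik(object$ode_fits)
  attr(ll, "df") <- sum(vapply(object$ode_fits, function(f)
    length(f$theta_self) + sum(lengths(f$theta_partner)), 0))
  class(ll) <- "logLik"
  ll
}

#' Predict component trajectories on the fitted habitat grid
#'
#' @param object a `"qdnet"` fit
#' @param taxon taxon id (default: all taxa)
#' @param ... ignored
#' @return for one taxon, its [decompose()] table; otherwise a named list
#'   of tables
#' @export
predict.qdnet <- function(object, taxon = NULL, ...) {
  if (!is.null(taxon)) return(decompose(object$ode_fits[[taxon]]))
  lapply(object$ode_fits, decompose)
}

#' Plot a fitted taxon's component decomposition
#'
#' Observed abundance, fitted trajectory, and the independent plus summed
#' positive/negative dependent components along the habitat-index axis.
#'
#' @param x a `"qdnet"` fit
#' @param taxon taxon id (default: first taxon)
#' @param ... passed to [graphics::plot()]
#' @export
plot.qdnet <- function(x, taxon = taxa(x$abund)[1], ...) {
  d <- decompose(x$ode_fits[[taxon]])
  rng <- range(d$observed, d$fitted, d$independent,
               d$dependent_pos, d$dependent_neg)
  graphics::plot(d$H, d$observed, pch = 16, col = "grey40",
                 xlab = "habitat index", ylab = "abundance / component",
                 ylim = rng, main = taxon, ...)
  graphics::lines(d$H, d$fitted, lwd = 2)
  graphics::lines(d$H, d$independent, col = "purple", lwd = 2)
  graphics::lines(d$H, d$dependent_pos, col = "firebrick", lwd = 2)
  graphics::lines(d$H, d$dependent_neg, col = "steelblue", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", "purple", "firebrick", "steelblue"),
                   legend = c("fitted", "independent", "dependent (+)",
                              "dependent (-)"))
  invisible(x)
}

#' Simulate abundance matrices from a fitted model
#'
#' Draws Gaussian noise around the fitted per-taxon trajectories using the
#' estimated residual variances; negative draws are truncated at 0.
#'
#' @param object a `"qdnet"` fit
#' @param nsim number of simulated matrices
#' @param seed optional RNG seed
#' @param ... ignored
#' @return list of `abund` objects
#' @export
simulate.qdnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sds <- sqrt(vapply(object$ode_fits, function(f) f$sigma2, 0))
  ids <- object$ode_fits[[1]]$sample_ids
  lapply(seq_len(nsim), function(k) {
    Y <- pmax(mu + matrix(stats::rnorm(length(mu), 0,
                                       rep(sds, each = nrow(mu))),
                          nrow(mu)), 0)
    rownames(Y) <- ids
    abundance_matrix(Y, drop_empty = FALSE)
  })
}
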