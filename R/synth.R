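# Synthetic abundance generator. The generative laws mirror the model:
# every taxon follows a power-law baseline alpha_j H^beta_j (its
# independent component), and planted interactions are themselves power
# laws: a directed edge j' -> j multiplies the focal's abundance by
# (y_j' / g_j')^tau, i.e. interactions are linear on the log scale, the
# same scale on which the allometric law lives. The community is
# assembled sequentially along a random order (the planted network is a
# DAG), so every focal responds to its partners' final realized
# abundances — the same quantities the inference stages observe. The
# truth bundle records the planted adjacency, module labels, per-taxon
# component tables at the sample points, and realized signal-to-noise
# ratios.

#' Configuration for the synthetic abundance generator
#'
#' @param n_samples,n_taxa dimensions of the generated matrix
#' @param n_modules planted module count; module centers are spread evenly
#'   over `beta_range` with small per-taxon jitter
#' @param H_range habitat-index range; indices are drawn log-uniformly
#'   (communities span orders of magnitude in total abundance)
#' @param beta_range range of scaling exponents (most taxa increase with
#'   habitat index, a minority decrease)
#' @param alpha,beta optional explicit per-taxon parameter vectors
#' @param d planted partners per focal taxon (`d = 0` for no
#'   interactions); the community is assembled in a random order and each
#'   taxon draws its partners among already-assembled taxa, so the planted
#'   network is acyclic and the first-assembled taxa carry fewer links
#' @param strength_range magnitudes of planted edge strengths: an edge of
#'   strength s shifts the focal's log abundance by s standard deviations
#'   of the partner's log abundance
#' @param promote_prob probability that a planted edge is a promotion
#'   (positive); the rest are inhibitions
#' @param noise list: `sigma_log` (lognormal process/measurement noise sd
#'   on the log scale, default 0.2), `sigma_add` (additive Gaussian sd,
#'   scalar or per-taxon, default 0; draws truncated at 0), or `snr`
#'   (sets `sigma_log` to sqrt(d) x mean strength / snr, the value at
#'   which the planted dependent signal is snr times the noise on the log
#'   scale)
#' @param contexts `NULL`, or a list with `sizes` (per-context sample
#'   counts summing to `n_samples`), and optionally `flip_edges` (number
#'   of planted edges whose sign flips in the last context) and
#'   `strength_mult` (per-context multiplier on all edge strengths)
#' @param seed mandatory RNG seed
#' @return class `"generator_config"` list
#' @export
generator_config <- function(n_samples, n_taxa, n_modules = 1,
                             H_range = c(10, 1000),
                             beta_range = c(-1, 1.5),
                             alpha = NULL, beta = NULL,
                             d = 2, strength_range = c(0.4, 0.8),
                             promote_prob = 0.5,
                             noise = list(sigma_log = 0.2),
                             contexts = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(d < n_taxa, n_samples >= 4, all(is.finite(strength_range)))
  if (!is.null(contexts) && sum(contexts$sizes) != n_samples)
    stop("context sizes must sum to n_samples")
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 n_modules = n_modules, H_range = H_range,
                 beta_range = beta_range, alpha = alpha, beta = beta,
                 d = d, strength_range = strength_range,
                 promote_prob = promote_prob, noise = noise,
                 contexts = contexts, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic abundance dataset with known truth
#'
#' @param cfg a [generator_config()]
#' @return list with `abund` (an `abund` object, context labels attached
#'   when contexts are configured) and `truth` (drawn habitat indices,
#'   per-taxon `alpha`/`beta`, `modules`, planted `adjacency` with
#'   per-context signs and strengths, per-taxon `independent` and
#'   `dependent` component tables at the sample points, realized `snr`,
#'   and the realized-vs-drawn habitat-index discrepancy)
#' @export
generate_abundance <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_taxa
  H <- sort(exp(stats::runif(n, log(cfg$H_range[1]), log(cfg$H_range[2]))))
  # module centers and per-taxon power-law parameters
  modules <- sort(rep_len(seq_len(cfg$n_modules), m))
  if (is.null(cfg$beta)) {
    if (cfg$n_modules > 1) {
      # tight per-module curve families (for module-detection studies)
      centers_b <- seq(cfg$beta_range[1], cfg$beta_range[2],
                       length.out = cfg$n_modules)
      beta <- centers_b[modules] + stats::rnorm(m, 0, 0.005)
    } else {
      # diverse community: exponents spread over the whole range
      beta <- stats::runif(m, cfg$beta_range[1], cfg$beta_range[2])
    }
  } else beta <- rep_len(cfg$beta, m)
  if (is.null(cfg$alpha)) {
    if (cfg$n_modules > 1) {
      centers_a <- exp(seq(log(0.2), log(2), length.out = cfg$n_modules))
      alpha <- centers_a[modules] * exp(stats::rnorm(m, 0, 0.005))
    } else {
      alpha <- exp(stats::runif(m, log(0.05), log(2)))
    }
  } else alpha <- rep_len(cfg$alpha, m)
  taxon_ids <- sprintf("T%02d", seq_len(m))
  base <- vapply(seq_len(m), function(j) alpha[j] * H^beta[j], numeric(n))
  colnames(base) <- taxon_ids
  if (!all(is.finite(base)))
    stop("baseline blow-up; use smaller exponents or a narrower H range")

  # noise level; the snr option calibrates it to the planted log-scale
  # dependent signal (per-edge log contributions have sd = strength)
  sig_log <- cfg$noise$sigma_log %||% 0.2
  if (!is.null(cfg$noise$snr) && cfg$d > 0)
    sig_log <- sqrt(cfg$d) * mean(cfg$strength_range) / cfg$noise$snr
  eps <- matrix(stats::rnorm(n * m, 0, sig_log), n, m)

  # context plan
  ctx_labels <- NULL
  csizes <- NULL
  if (!is.null(cfg$contexts)) {
    csizes <- cfg$contexts$sizes
    cnames <- names(csizes) %||% sprintf("C%d", seq_along(csizes))
    names(csizes) <- cnames
    ctx_labels <- sample(rep(cnames, csizes))
  }

  # sequential assembly: each focal draws partners among the taxa already
  # assembled (planted network is a DAG) and responds to their realized
  # log abundance, one sd of which shifts the focal's log abundance by
  # the edge strength
  resample <- function(x, k) x[sample.int(length(x), k)]
  ordr <- sample(m)
  Y <- matrix(0, n, m, dimnames = list(sprintf("S%02d", seq_len(n)),
                                       taxon_ids))
  U <- matrix(0, n, m)
  adj <- NULL
  shares <- lapply(seq_len(m), function(j) matrix(0, n, 0))
  for (k in seq_len(m)) {
    j <- ordr[k]
    avail <- ordr[seq_len(k - 1)]
    dd <- min(cfg$d, length(avail))
    if (dd > 0) {
      p <- resample(avail, dd)
      sgn <- ifelse(stats::runif(dd) < cfg$promote_prob, 1L, -1L)
      s <- stats::runif(dd, cfg$strength_range[1], cfg$strength_range[2])
      sh <- vapply(seq_len(dd), function(q) {
        lp <- log(Y[, p[q]])
        sgn[q] * s[q] * (lp - mean(lp)) / max(stats::sd(lp), 1e-12)
      }, numeric(n))
      colnames(sh) <- taxon_ids[p]
      shares[[j]] <- sh
      U[, j] <- rowSums(sh)
      adj <- rbind(adj, data.frame(from = taxon_ids[p], to = taxon_ids[j],
                                   sign = sgn, strength = s,
                                   stringsAsFactors = FALSE))
    }
    Y[, j] <- base[, j] * exp(U[, j] + eps[, j])
    if (!all(is.finite(Y[, j])))
      stop("interaction blow-up; use smaller strengths")
  }

  # per-context adjacency: sign flips / strength multipliers applied to
  # the rows of the affected context
  ctx_adj <- list(all = adj)
  flipped <- NULL
  if (!is.null(ctx_labels)) {
    ctx_adj <- stats::setNames(rep(list(adj), length(csizes)),
                               names(csizes))
    if (!is.null(adj)) {
      mult <- cfg$contexts$strength_mult %||% rep(1, length(csizes))
      for (k in seq_along(csizes))
        ctx_adj[[k]]$strength <- adj$strength * mult[k]
      nf <- cfg$contexts$flip_edges %||% 0
      if (nf > 0) {
        flipped <- sample(nrow(adj), min(nf, nrow(adj)))
        last <- length(csizes)
        ctx_adj[[last]]$sign[flipped] <- -ctx_adj[[last]]$sign[flipped]
      }
      # re-apply the modified shares on each context's rows
      for (k in seq_along(csizes)) {
        rows <- which(ctx_labels == names(csizes)[k])
        A <- ctx_adj[[k]]
        for (j in seq_len(m)) {
          sh <- shares[[j]]
          if (!ncol(sh)) next
          for (cn in colnames(sh)) {
            r0 <- adj$sign[adj$to == taxon_ids[j] & adj$from == cn] *
              adj$strength[adj$to == taxon_ids[j] & adj$from == cn]
            r1 <- A$sign[A$to == taxon_ids[j] & A$from == cn] *
              A$strength[A$to == taxon_ids[j] & A$from == cn]
            if (abs(r0) > 1e-12 && r1 != r0)
              sh[rows, cn] <- sh[rows, cn] * r1 / r0
          }
          shares[[j]] <- sh
        }
      }
      for (j in seq_len(m)) if (ncol(shares[[j]])) {
        U[, j] <- rowSums(shares[[j]])
        Y[, j] <- base[, j] * exp(U[, j] + eps[, j])
      }
    }
  }

  # truth components on the original scale: the noiseless-with-interaction
  # signal is base * exp(U); its dependent part is split across edges in
  # proportion to their log-scale shares
  sig_add <- rep_len(cfg$noise$sigma_add %||% 0, m)
  if (any(sig_add > 0))
    Y <- pmax(Y + vapply(seq_len(m), function(j)
      stats::rnorm(n, 0, sig_add[j]), numeric(n)), 0)
  signal <- base * exp(U)
  dep_all <- signal - base
  by_edge <- lapply(seq_len(m), function(j) {
    sh <- shares[[j]]
    if (!ncol(sh)) return(sh)
    tot <- rowSums(abs(sh))
    (sh / ifelse(tot > 0, tot, 1)) * abs(dep_all[, j])
  })
  names(by_edge) <- taxon_ids
  noise_sd <- apply(Y - signal, 2, stats::sd)
  snr <- ifelse(noise_sd > 0, apply(dep_all, 2, stats::sd) / noise_sd, Inf)
  ab <- abundance_matrix(Y, context = ctx_labels, drop_empty = FALSE)
  truth <- list(H = H, alpha = alpha, beta = beta,
                modules = stats::setNames(modules, taxon_ids),
                adjacency = ctx_adj, flipped_edges = flipped,
                assembly_order = taxon_ids[ordr],
                independent = base, dependent = dep_all,
                dependent_by_edge = by_edge, signal = signal,
                log_effects = U, sigma_log = sig_log,
                snr = stats::setNames(snr, taxon_ids),
                habitat_discrepancy = rowSums(Y) - H,
                config = cfg)
  list(abund = ab, truth = truth)
}

#' Ready-made generator scenarios mimicking a gut spatial-mapping design
#'
#' `"phylum17"`: 23 samples x 17 taxa (16 abundant phyla plus an "other"
#' bin). `"species65_7mod"`: 23 samples x 65 taxa in 7 planted modules.
#' `"two_context"`: 23 samples in two contexts of 19 and 4 samples (a
#' case-heavy case/control split), with planted sign flips between
#' contexts.
#'
#' @param name scenario name
#' @param seed RNG seed
#' @return a [generator_config()]
#' @export
scenario <- function(name = c("phylum17", "species65_7mod", "two_context"),
                     seed = 1) {
  name <- match.arg(name)
  switch(name,
    phylum17 = generator_config(n_samples = 23, n_taxa = 17, n_modules = 1,
                                d = 2, seed = seed),
    species65_7mod = generator_config(n_samples = 23, n_taxa = 65,
                                      n_modules = 7, d = 2, seed = seed),
    two_context = generator_config(n_samples = 23, n_taxa = 10, d = 2,
                                   contexts = list(sizes = c(UC = 19, HC = 4),
                                                   flip_edges = 3),
                                   seed = seed))
}
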