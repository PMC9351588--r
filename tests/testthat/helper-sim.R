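# Shared fixtures: everything is generated in code at test time.

toy_matrix <- function(n = 4, m = 4, value = 1) {
  matrix(value, n, m, dimnames = list(sprintf("s%d", seq_len(n)),
                                      sprintf("t%d", seq_len(m))))
}

# support-recovery F1 for one focal taxon
f1_score <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (!length(selected) && !length(truth)) return(1)
  p <- if (length(selected)) tp / length(selected) else 0
  r <- if (length(truth)) tp / length(truth) else 1
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# adjusted Rand index (independent implementation for cluster checks)
ari <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  sij <- sc(tab); si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
  stot <- choose(sum(tab), 2)
  exp_ <- si * sj / stot
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# plant a known log-linear influence of `partner` on `focal` in an
# interaction-free simulated matrix
plant_edge <- function(M, focal, partner, strength, sign = 1) {
  lp <- log(M$values[, partner])
  V <- M$values
  V[, focal] <- V[, focal] *
    exp(sign * strength * (lp - mean(lp)) / stats::sd(lp))
  abundance_matrix(V, context = M$context, position = M$position,
                   subject = M$subject, drop_empty = FALSE)
}

empty_links <- function(M) {
  structure(lapply(taxa(M), function(t) list(selected = character(0))),
            names = taxa(M))
}
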