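#' Encode qdODE fits as a signed, weighted, directed network
#'
#' Nodes are taxa weighted by their mean independent component over the
#' evaluation samples; a directed edge j' -> j exists exactly when j' was
#' selected as a partner of j. The edge magnitude is the mean absolute
#' dependent component G_jj' over the same samples, and its sign is the
#' direction of the fitted response of j to j' (promotion or inhibition). Edges with |weight| below the
#' neutrality threshold epsilon keep sign 0 (neutral): they still enter
#' pair classification but are excluded from role-degree counts.
#' Restricting `sample_subset` to one sample yields the instantaneous
#' ("personalized") network at that sample.
#'
#' @param fits a `"qdode_fit_list"`
#' @param sample_subset sample ids (or positions on the sorted grid) over
#'   which components are averaged; default all samples
#' @param epsilon neutrality threshold; default 0.05 x mean abundance of
#'   the target taxon (per-edge), a single number applies globally
#' @param agg `"mean"` (default) or `"terminal"` (value at the largest H
#'   in the subset)
#' @param scope free-text label stored on the network (e.g. a position or
#'   context name)
#' @return class `"interaction_network"`: list with `nodes` (taxon,
#'   weight, mean_abundance), `edges` (from, to, weight, strength, sign),
#'   `epsilon`, `scope`
#' @export
build_network <- function(fits, sample_subset = NULL, epsilon = NULL,
                          agg = c("mean", "terminal"), scope = "all") {
  agg <- match.arg(agg)
  stopifnot(inherits(fits, "qdode_fit_list"))
  ids <- fits[[1]]$sample_ids
  if (is.null(sample_subset)) {
    idx <- seq_along(ids)
  } else if (is.character(sample_subset)) {
    idx <- match(sample_subset, ids)
    if (anyNA(idx)) stop("unknown sample ids in subset")
  } else idx <- sample_subset
  if (!length(idx)) stop("empty sample subset")
  pick <- function(v) if (agg == "mean") mean(v[idx]) else v[max(idx)]
  nodes <- data.frame(
    taxon = names(fits),
    weight = vapply(fits, function(f) pick(f$independent_traj), 0),
    mean_abundance = vapply(fits, function(f) mean(f$observed[idx]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  eps_for <- function(target) {
    if (!is.null(epsilon)) return(epsilon)
    0.05 * nodes$mean_abundance[nodes$taxon == target]
  }
  edges <- do.call(rbind, lapply(fits, function(f) {
    if (!length(f$dependent_traj)) return(NULL)
    # magnitude: aggregated |dependent component|; sign: direction of the
    # fitted response to the partner (mean-of-component is sign-ambiguous
    # for fluctuation-driven interactions)
    mag <- vapply(f$dependent_traj, function(v) pick(abs(v)), 0)
    dirs <- sign(f$partner_slopes[names(f$dependent_traj)])
    dirs[dirs == 0] <- 1
    w <- unname(mag * dirs)
    data.frame(from = names(f$dependent_traj), to = f$focal,
               weight = w, strength = abs(w),
               sign = ifelse(abs(w) < eps_for(f$focal), 0L, as.integer(sign(w))),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), strength = numeric(),
                        sign = integer(), stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop("self-edge produced; invalid links")
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 scope = scope, agg = agg, n_samples = length(idx)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network [%s]: %d nodes, %d edges (%d non-neutral)\n",
              x$scope, nrow(x$nodes), nrow(x$edges), sum(x$edges$sign != 0)))
  invisible(x)
}

# Signed-pair label table. fwd = sign of A's effect on B (edge A -> B),
# rev = sign of B's effect on A.
.pair_label <- function(fwd, rev) {
  if (fwd > 0 && rev > 0) return("mutualism")
  if (fwd < 0 && rev < 0) return("antagonism")
  if (fwd > 0 && rev == 0) return("commensalism")
  if (fwd == 0 && rev > 0) return("commensalism")
  if (fwd < 0 && rev == 0) return("amensalism")
  if (fwd == 0 && rev < 0) return("amensalism")
  if (fwd < 0 && rev > 0) return("parasitism")
  if (fwd > 0 && rev < 0) return("altruism")
  "neutral"
}

#' Classify the ecological interaction type of a taxon pair
#'
#' Pure function of the two signed, thresholded edge weights: reciprocal
#' promotion is mutualism and reciprocal inhibition antagonism; one-sided
#' promotion (the partner neutral) is commensalism and one-sided inhibition
#' amensalism; A inhibiting B while B promotes A is parasitism (of A on B),
#' the reverse altruism; both neutral is neutral. A missing edge counts as
#' sign 0.
#'
#' @param net an `"interaction_network"`
#' @param A,B distinct taxon ids
#' @return class `"pair_classification"`: the two signs, the label, and a
#'   directionality note
#' @export
classify_pair <- function(net, A, B) {
  stopifnot(A != B)
  e <- net$edges
  sgn <- function(from, to) {
    hit <- e$from == from & e$to == to
    if (any(hit)) e$sign[hit][1] else 0L
  }
  fwd <- sgn(A, B); rev <- sgn(B, A)
  lab <- .pair_label(fwd, rev)
  note <- switch(lab,
    commensalism = sprintf("%s promotes %s", if (fwd > 0) A else B,
                           if (fwd > 0) B else A),
    amensalism = sprintf("%s inhibits %s", if (fwd < 0) A else B,
                         if (fwd < 0) B else A),
    parasitism = sprintf("%s inhibits %s; %s promotes %s",
                         if (fwd < 0) A else B, if (fwd < 0) B else A,
                         if (fwd < 0) B else A, if (fwd < 0) A else B),
    altruism = sprintf("%s promotes %s; %s inhibits %s",
                       if (fwd > 0) A else B, if (fwd > 0) B else A,
                       if (fwd > 0) B else A, if (fwd > 0) A else B),
    "")
  structure(list(pair = c(A, B), forward_sign = fwd, reverse_sign = rev,
                 label = lab, note = note),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("%s -- %s: %s (%+d / %+d)%s\n", x$pair[1], x$pair[2], x$label,
              x$forward_sign, x$reverse_sign,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Classify all unordered taxon pairs of a network
#' @param net an `"interaction_network"`
#' @return data.frame (A, B, forward_sign, reverse_sign, label)
#' @export
classify_all_pairs <- function(net) {
  tx <- net$nodes$taxon
  if (length(tx) < 2)
    return(data.frame(A = character(), B = character(),
                      forward_sign = integer(), reverse_sign = integer(),
                      label = character(), stringsAsFactors = FALSE))
  pr <- utils::combn(tx, 2)
  do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
    p <- classify_pair(net, pr[1, k], pr[2, k])
    data.frame(A = p$pair[1], B = p$pair[2],
               forward_sign = p$forward_sign, reverse_sign = p$reverse_sign,
               label = p$label, stringsAsFactors = FALSE)
  }))
}

#' Node roles: leader, hub (keystone), solitary
#'
#' On the thresholded graph (neutral edges excluded): active links are
#' outgoing edges, passive links incoming. A leader has more active than
#' passive links; a hub's active links exceed the mean total connectivity
#' (mean over nodes of out + in); a solitary node has fewer total links
#' than the mean (strict inequalities, so an edgeless network has no
#' solitary nodes).
#'
#' @param net an `"interaction_network"`
#' @return data.frame (taxon, out_degree, in_degree, leader, hub, solitary,
#'   ordinary)
#' @export
classify_roles <- function(net) {
  e <- net$edges[net$edges$sign != 0, , drop = FALSE]
  tx <- net$nodes$taxon
  outd <- vapply(tx, function(t) sum(e$from == t), 0L)
  ind <- vapply(tx, function(t) sum(e$to == t), 0L)
  meanconn <- mean(outd + ind)
  leader <- outd > ind
  hub <- outd > meanconn
  solitary <- (outd + ind) < meanconn
  data.frame(taxon = tx, out_degree = outd, in_degree = ind,
             leader = leader, hub = hub, solitary = solitary,
             ordinary = !(leader | hub | solitary),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert to an igraph object
#' @param net an `"interaction_network"`
#' @return an [igraph::graph_from_data_frame()] graph with node weight and
#'   edge weight/sign/strength attributes
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Export a network as GraphML and an edge-list TSV
#' @param net an `"interaction_network"`
#' @param graphml,edges output paths (skipped when `NULL`)
#' @export
write_network <- function(net, graphml = NULL, edges = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  if (!is.null(edges))
    utils::write.table(net$edges, edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}

#' Assemble a two-layer (module + within-module) network
#'
#' The coarse layer is a network over module-mean abundance profiles; the
#' fine layer holds one network per module over its member taxa
#' (single-taxon modules yield a node-only network). The same neutrality
#' threshold rule is applied across layers.
#'
#' @param M an `abund` object
#' @param assignment a [functional_cluster()] result
#' @param order LOP degree passed to selection and qdODE stages
#' @param epsilon neutrality threshold (default per-edge rule)
#' @param ... further arguments to [select_links()] / [fit_qdode()]
#' @return list with `coarse` (module-level `"interaction_network"`) and
#'   `fine` (named list of per-module networks)
#' @export
build_multilayer <- function(M, assignment, order = 3, epsilon = NULL, ...) {
  prof <- module_profiles(M, assignment)
  run_net <- function(sub, scope) {
    fits <- fit_power_all(sub)
    links <- select_links(sub, order = order, fits = fits, ...)
    ode <- fit_qdode(sub, links, order = order, fits = fits)
    build_network(ode, epsilon = epsilon, scope = scope)
  }
  coarse <- run_net(prof, "modules")
  fine <- lapply(sort(unique(assignment$labels)), function(l) {
    members <- names(assignment$labels)[assignment$labels == l]
    if (length(members) < 2) {
      message(sprintf("module %d has a single taxon; node-only network", l))
      sub <- M[, members]
      fits <- fit_power_all(sub)
      links <- structure(stats::setNames(
        list(list(selected = character(0))), members),
        class = "link_selection_list")
      ode <- fit_qdode(sub, links, order = order, fits = fits)
      return(build_network(ode, epsilon = epsilon,
                           scope = sprintf("module%d", l)))
    }
    run_net(M[, members], sprintf("module%d", l))
  })
  names(fine) <- sprintf("module%d", sort(unique(assignment$labels)))
  list(coarse = coarse, fine = fine)
}
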