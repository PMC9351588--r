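make_fits <- function(weights, n = 6) {
  # fabricate a qdode_fit_list with prescribed mean dependent components;
  # sign conventions follow the response slopes
  taxa_ids <- unique(c(weights$to, weights$from))
  fits <- lapply(taxa_ids, function(tx) {
    dep <- weights[weights$to == tx, , drop = FALSE]
    dt <- lapply(seq_len(nrow(dep)), function(i) rep(dep$w[i], n))
    names(dt) <- dep$from
    structure(list(focal = tx,
                   sample_ids = sprintf("s%d", seq_len(n)),
                   grid = seq_len(n),
                   independent_traj = rep(1, n),
                   dependent_traj = dt,
                   partner_slopes = stats::setNames(sign(dep$w), dep$from),
                   observed = rep(1, n), fitted = rep(1, n),
                   sigma2 = 0.1, rss = 0, z = rep(1, n), converged = TRUE),
              class = "qdode_fit")
  })
  names(fits) <- taxa_ids
  structure(fits, class = "qdode_fit_list")
}

test_that("all nine sign combinations map onto exactly the seven labels", {
  combos <- expand.grid(fwd = c(-1L, 0L, 1L), rev = c(-1L, 0L, 1L))
  labels <- mapply(function(f, r) qdnet:::.pair_label(f, r),
                   combos$fwd, combos$rev)
  expect_setequal(unique(labels),
                  c("mutualism", "antagonism", "commensalism", "amensalism",
                    "parasitism", "altruism", "neutral"))
  expect_identical(qdnet:::.pair_label(1, 1), "mutualism")
  expect_identical(qdnet:::.pair_label(-1, -1), "antagonism")
  expect_identical(qdnet:::.pair_label(1, 0), "commensalism")
  expect_identical(qdnet:::.pair_label(0, 1), "commensalism")
  expect_identical(qdnet:::.pair_label(-1, 0), "amensalism")
  expect_identical(qdnet:::.pair_label(0, -1), "amensalism")
  expect_identical(qdnet:::.pair_label(-1, 1), "parasitism")
  expect_identical(qdnet:::.pair_label(1, -1), "altruism")
  expect_identical(qdnet:::.pair_label(0, 0), "neutral")
})

test_that("pair classification is symmetric under swapping with transposed labels", {
  w <- data.frame(from = c("A", "B"), to = c("B", "A"), w = c(-0.5, 0.7))
  net <- build_network(make_fits(w), epsilon = 0.1)
  ab <- classify_pair(net, "A", "B")
  ba <- classify_pair(net, "B", "A")
  expect_identical(ab$label, "parasitism")
  expect_identical(ba$label, "altruism")
  w2 <- data.frame(from = "A", to = "B", w = 0.5)
  net2 <- build_network(make_fits(w2), epsilon = 0.1)
  expect_identical(classify_pair(net2, "A", "B")$label, "commensalism")
  expect_identical(classify_pair(net2, "B", "A")$label, "commensalism")
})

test_that("edges below the neutrality threshold keep sign zero", {
  w <- data.frame(from = c("A", "C"), to = c("B", "B"), w = c(0.5, 0.01))
  net <- build_network(make_fits(w), epsilon = 0.1)
  e <- net$edges
  expect_equal(e$sign[e$from == "A"], 1L)
  expect_equal(e$sign[e$from == "C"], 0L)
  expect_identical(classify_pair(net, "C", "B")$label, "neutral")
})

test_that("node roles follow the degree rules", {
  w <- data.frame(from = c("A", "A", "A", "B"),
                  to = c("B", "C", "D", "A"), w = 1)
  roles <- classify_roles(build_network(make_fits(w), epsilon = 0.1))
  a <- roles[roles$taxon == "A", ]
  expect_true(a$leader)      # out 3 > in 1
  expect_true(a$hub)         # out 3 > mean connectivity 2
  cd <- roles[roles$taxon %in% c("C", "D"), ]
  expect_true(all(cd$solitary))  # total 1 < mean 2
})

test_that("an edgeless network has only ordinary nodes", {
  sim <- generate_abundance(generator_config(15, 4, d = 0, seed = 71))
  M <- sim$abund
  ode <- fit_qdode(M, empty_links(M), order = 1)
  net <- build_network(ode)
  expect_equal(nrow(net$edges), 0L)
  roles <- classify_roles(net)
  expect_true(all(roles$ordinary))
  expect_false(any(roles$solitary))
})

test_that("role flags are invariant to uniform rescaling with epsilon rescaled", {
  w <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                  w = c(0.5, -0.2, 0.05))
  r1 <- classify_roles(build_network(make_fits(w), epsilon = 0.1))
  w2 <- w; w2$w <- w2$w * 10
  r2 <- classify_roles(build_network(make_fits(w2), epsilon = 1))
  expect_identical(r1, r2)
})

test_that("edge support comes from selection, not from the evaluation subset", {
  sim <- generate_abundance(generator_config(30, 5, d = 2, seed = 72))
  fit <- qdnet(sim$abund, order = 2)
  full <- build_network(fit$ode_fits)
  sub <- build_network(fit$ode_fits, sample_subset = samples(sim$abund)[5])
  key <- function(e) paste(e$from, e$to)
  expect_setequal(key(full$edges), key(sub$edges))
  expect_equal(sub$n_samples, 1L)
})

test_that("networks export to igraph, GraphML and edge lists", {
  w <- data.frame(from = c("A", "B"), to = c("B", "C"), w = c(1, -1))
  net <- build_network(make_fits(w), epsilon = 0.1)
  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, edges = tsv)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  expect_equal(nrow(utils::read.delim(tsv)), 2L)
})

test_that("multilayer assembly yields a coarse module net plus per-module nets", {
  sim <- generate_abundance(generator_config(24, 9, n_modules = 3, d = 1,
                                             noise = list(sigma_log = 0.1),
                                             seed = 73))
  M <- sim$abund
  cl <- functional_cluster(M, 3, seed = 1)
  ml <- build_multilayer(M, cl, order = 1)
  expect_equal(nrow(ml$coarse$nodes), 3L)
  expect_length(ml$fine, 3L)
  for (nm in names(ml$fine)) {
    members <- sum(cl$labels == as.integer(sub("module", "", nm)))
    expect_equal(nrow(ml$fine[[nm]]$nodes), members)
    expect_lte(nrow(ml$fine[[nm]]$edges), members * (members - 1))
  }
})
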