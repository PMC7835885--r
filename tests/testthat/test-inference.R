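test_that("CUG conditioning on edges is degenerate for the edge count", {
  g <- random_weighted_graph(10, 20, seed = 1)
  res <- cug_test(g, function(x) igraph::ecount(x), mode = "edges", R = 99,
                  seed = 1)
  expect_true(all(res$null_draws == 20))
  expect_equal(res$p_greater, 1)
  expect_equal(res$p_lower, 1)
})

test_that("CUG draws conditioned on edges keep the observed edge count", {
  g <- random_weighted_graph(12, 30, seed = 2)
  res <- cug_test(g, function(x) igraph::ecount(x), mode = "edges", R = 200,
                  seed = 3)
  expect_true(all(res$null_draws == 30))
})

test_that("a complete graph is extreme under size conditioning", {
  k5 <- unit_weights(igraph::make_full_graph(5))
  res <- cug_test(k5, net_density, mode = "size", R = 999, seed = 7)
  # P(one G(5, 1/2) draw is complete) = 2^-10; observed density 1 tops all
  expect_lte(res$p_greater, 2 / 1000)
  expect_gt(res$p_lower, 0.99)
})

test_that("planted structure shows excess transitivity under the CUG null", {
  sim <- generate_cohort(default_cohort_spec(seed = 6, n_subjects = 120))
  net <- build_network(spearman_matrix(sim$table), 0.001)
  res <- cug_test(net, function(g) igraph::transitivity(g, type = "global"),
                  mode = "edges", R = 199, seed = 2)
  expect_lte(res$p_greater, 0.01)
})

test_that("gcor matches its closed-form anchors", {
  g <- random_weighted_graph(12, 25, seed = 4)
  expect_equal(gcor(g, g), 1)
  # a binary graph against its complement anti-aligns perfectly
  gb <- igraph::sample_gnm(10, 22, directed = FALSE)
  igraph::V(gb)$name <- letters[1:10]
  igraph::E(gb)$weight <- 1
  comp <- igraph::complementer(gb)
  igraph::E(comp)$weight <- 1
  expect_equal(gcor(gb, comp), -1)
  # independent graphs: mean gcor near 0
  vals <- vapply(1:100, function(s) {
    g1 <- random_weighted_graph(30, 80, seed = 1000 + s)
    g2 <- random_weighted_graph(30, 80, seed = 2000 + s)
    gcor(g1, g2)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("QAP self-comparison is maximally significant and permutation-invariant", {
  g <- random_weighted_graph(12, 25, seed = 5)
  q <- qap_test(g, g, R = 199, seed = 8)
  expect_equal(q$observed, 1)
  expect_lte(q$p_greater, (1 + sum(q$null_draws >= 1)) / 200)
  expect_gt(q$p_greater, 0)  # add-one smoothing: never exactly 0
  # the null distribution is non-degenerate for an asymmetric graph
  star <- unit_star(5)
  qs <- qap_test(star, star, R = 99, seed = 1)
  expect_gt(stats::sd(qs$null_draws), 0)
})

test_that("QAP keeps its nominal type-I rate on independent graphs", {
  pvals <- vapply(1:100, function(s) {
    g1 <- random_weighted_graph(20, 60, seed = 3000 + s)
    g2 <- random_weighted_graph(20, 60, seed = 4000 + s)
    qap_test(g1, g2, R = 99, seed = s)$p_greater
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("shared subgraphs preserve edges and attributes", {
  g <- random_weighted_graph(10, 25, seed = 9)
  full <- shared_subgraph(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(full), 25)
  el <- igraph::as_edgelist(g)
  pair <- el[1, ]
  sub <- shared_subgraph(g, pair)
  expect_equal(igraph::ecount(sub), 1)
  expect_equal(igraph::E(sub)$weight,
               igraph::E(g)$weight[igraph::get_edge_ids(g, pair)])
  # induced edge set = edges with both endpoints inside
  ids <- igraph::V(g)$name[1:6]
  sub6 <- shared_subgraph(g, ids)
  expect_equal(igraph::ecount(sub6),
               sum(el[, 1] %in% ids & el[, 2] %in% ids))
  expect_error(shared_subgraph(g, "nope"), "unknown node id")
})

test_that("comparing a network with itself gives perfect agreement", {
  sim <- generate_cohort(default_cohort_spec(seed = 3, n_subjects = 100))
  net <- build_network(spearman_matrix(sim$table), 0.001)
  part <- louvain_communities(net, seed = 2)
  cmp <- compare_networks(net, net, clusterings = list(part, part), R = 99)
  expect_equal(cmp$node_strength$rho, 1)
  expect_equal(cmp$eigencentrality$rho, 1)
  expect_equal(cmp$edge_weight$rho, 1)
  expect_equal(cmp$gcor, 1)
  expect_equal(cmp$cluster_agreement$rand, 1)
  expect_equal(cmp$cluster_agreement$vi, 0)
  # disjoint node sets: error
  g1 <- unit_path(c("a", "b", "c"))
  g2 <- unit_path(c("x", "y", "z"))
  expect_error(compare_networks(g1, g2), "fewer than 3")
})

test_that("eigencentrality replicates across cohorts better than flow betweenness", {
  # two cohorts drawn from the same spec with different seeds: the radial
  # measure should correlate across replicates more often than the medial
  wins <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    spec <- function(seed) cohort_spec(
      n_subjects = 120,
      blocks = list(block_spec("b1", 7, 0.6), block_spec("b2", 6, 0.6),
                    block_spec("b3", 6, 0.6), block_spec("b4", 6, 0.6)),
      between_rho = 0.1, marginal_family = "lognormal", seed = seed)
    n1 <- build_network(spearman_matrix(generate_cohort(spec(9000 + r))$table),
                        0.001)
    n2 <- build_network(spearman_matrix(generate_cohort(spec(9500 + r))$table),
                        0.001)
    cmp <- compare_networks(n1, n2, R = 99, seed = r)
    if (is.na(cmp$flow_betweenness$rho) ||
        cmp$eigencentrality$rho > cmp$flow_betweenness$rho) wins <- wins + 1
  }
  expect_gte(wins, 0.8 * reps)
})
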