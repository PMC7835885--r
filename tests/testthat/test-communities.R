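test_that("Louvain recovers the two cliques and attains the exhaustive optimum", {
  g <- two_k4_bridge()
  part <- louvain_communities(g, seed = 3)
  planted <- new_partition(stats::setNames(rep(1:2, each = 4),
                                           igraph::V(g)$name))
  expect_equal(adjusted_rand_index(part, planted), 1)
  # exhaustive search over all Bell(8) = 4140 partitions
  best <- max(vapply(enumerate_partitions(8), function(m)
    oracle_modularity(g, m), numeric(1)))
  expect_equal(part$modularity, best, tolerance = 1e-12)
})

test_that("reported modularity equals the independent formula", {
  for (s in 1:4) {
    g <- random_weighted_graph(20, 45, seed = 20 + s)
    part <- louvain_communities(g, seed = s)
    expect_equal(part$modularity,
                 oracle_modularity(g, part$membership[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
  # one clique as a single community scores 0
  k5 <- unit_weights(igraph::make_full_graph(5))
  part <- louvain_communities(k5, seed = 1)
  expect_identical(max(part$membership), 1L)
  expect_equal(part$modularity, 0, tolerance = 1e-12)
})

test_that("Louvain and the planted partition satisfy the optimizer sanity bound", {
  sim <- generate_cohort(default_cohort_spec(seed = 13))
  corr <- spearman_matrix(sim$table)
  net <- build_network(corr, 0.001)
  part <- louvain_communities(net, seed = 13)
  expect_gte(part$modularity,
             modularity_value(net, sim$partition$membership) - 1e-9)
})

test_that("clustering is deterministic given the seed", {
  sim <- generate_cohort(default_cohort_spec(seed = 8, n_subjects = 100))
  net <- build_network(spearman_matrix(sim$table), 0.001)
  expect_identical(louvain_communities(net, seed = 5)$membership,
                   louvain_communities(net, seed = 5)$membership)
  expect_identical(infomap_communities(net, seed = 5)$membership,
                   infomap_communities(net, seed = 5)$membership)
})

test_that("the map equation ranks partitions and infomap minimizes it", {
  g <- two_k4_bridge()
  part <- infomap_communities(g, seed = 2)
  planted <- new_partition(stats::setNames(rep(1:2, each = 4),
                                           igraph::V(g)$name))
  expect_equal(adjusted_rand_index(part, planted), 1)
  one_module <- stats::setNames(rep(1, 8), igraph::V(g)$name)
  expect_lte(map_equation(g, part$membership),
             map_equation(g, one_module))
  # the returned partition beats (or ties) every candidate two-level
  # partition from the exhaustive list
  best <- min(vapply(enumerate_partitions(8), function(m)
    map_equation(g, stats::setNames(m, igraph::V(g)$name)), numeric(1)))
  expect_lte(map_equation(g, part$membership), best + 1e-9)
  # merging a single edge into one module shortens the description
  e1 <- unit_weights(igraph::graph_from_literal(a - b))
  expect_lt(map_equation(e1, c(a = 1, b = 1)),
            map_equation(e1, c(a = 1, b = 2)))
})

test_that("subclustering runs per community and never crosses boundaries", {
  # one community that is itself two cliques + bridge, one singleton
  g <- igraph::disjoint_union(two_k4_bridge(),
                              igraph::make_empty_graph(1, directed = FALSE))
  igraph::V(g)$name[9] <- "z"
  part <- new_partition(stats::setNames(c(rep(1, 8), 2), igraph::V(g)$name))
  subs <- subcluster(g, part, method = "louvain", seed = 4)
  expect_identical(names(subs), c("1", "2"))
  expect_identical(max(subs[["1"]]$membership), 2L)  # split into the cliques
  expect_identical(unname(subs[["2"]]$membership), 1L)
  expect_true(all(names(subs[["1"]]$membership) %in% letters[1:8]))
})

test_that("Rand index, adjusted Rand and VI match pair/entropy arithmetic", {
  p1 <- new_partition(stats::setNames(c(1, 1, 2, 2), letters[1:4]))
  p2 <- new_partition(stats::setNames(1:4, letters[1:4]))
  expect_equal(rand_index(p1, p1), 1)
  expect_equal(variation_of_information(p1, p1), 0)
  expect_equal(adjusted_rand_index(p1, p1), 1)
  expect_equal(rand_index(p1, p2), 4 / 6)
  expect_equal(variation_of_information(p1, p2), log(2))
  p3 <- new_partition(stats::setNames(1:3, c("x", "y", "z")))
  expect_error(rand_index(p1, p3), "different node sets")
})

test_that("cluster contraction preserves the inter-cluster edge multiset", {
  g <- two_k4_bridge()
  part <- new_partition(stats::setNames(rep(1:2, each = 4),
                                        igraph::V(g)$name))
  cg <- contract_clusters(g, part)
  expect_equal(igraph::vcount(cg), 2)
  expect_equal(igraph::ecount(cg), 1)
  expect_equal(sum(igraph::E(cg)$weight), 1)

  # three cross edges stay as parallel edges; weight total conserved
  h <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c", "a", "a", "b"),
               to   = c("b", "d", "c", "d", "d"),
               weight = c(1, 1, 0.2, 0.3, 0.4)),
    directed = FALSE)
  hp <- new_partition(stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d")))
  ch <- contract_clusters(h, hp)
  expect_equal(igraph::ecount(ch), 3)
  expect_equal(sum(igraph::E(ch)$weight), 0.9)
  expect_true(igraph::any_multiple(ch))

  # singleton partition keeps every edge; component partition keeps none
  singletons <- new_partition(stats::setNames(1:8, igraph::V(g)$name))
  expect_equal(igraph::ecount(contract_clusters(g, singletons)), 13)
  comp_part <- new_partition(stats::setNames(rep(1, 8), igraph::V(g)$name))
  expect_equal(igraph::ecount(contract_clusters(g, comp_part)), 0)
  # anchors are the strongest members
  expect_identical(sort(igraph::V(cg)$anchor), c("d", "e"))
})
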