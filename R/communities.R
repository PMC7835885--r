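# Community detection (Louvain, map equation), modularity, subclustering,
# partition-comparison metrics, and cluster contraction.

#' Construct a partition object
#'
#' @param membership named vector (node name -> community label); labels
#'   are relabeled to contiguous integers starting at 1.
#' @param modularity optional modularity score of the partition.
#' @param method text tag of the producing method.
#' @param seed integer seed used by the producing method.
#' @return an object of class `partition`.
#' @export
new_partition <- function(membership, modularity = NA_real_,
                          method = "manual", seed = NA_integer_) {
  if (is.null(names(membership)))
    stop_named("partition membership must be named by node")
  lab <- match(membership, unique(membership))
  structure(list(membership = stats::setNames(lab, names(membership)),
                 modularity = modularity, method = method, seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition (%s): %d nodes in %d communities, Q = %s\n",
              x$method, length(x$membership), max(x$membership),
              format(x$modularity, digits = 4)))
  invisible(x)
}

#' Weighted modularity of a membership
#'
#' Evaluates `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j)`
#' directly on the weighted adjacency, independent of any community
#' detection routine.
#'
#' @param net an undirected weighted `igraph` network.
#' @param membership named community labels covering all nodes.
#' @return modularity in `[-0.5, 1]`.
#' @export
modularity_value <- function(net, membership) {
  W <- weighted_adjacency(ensure_names(net))
  m2 <- sum(W)
  if (m2 == 0) return(NA_real_)
  memb <- membership[rownames(W)]
  s <- rowSums(W)
  same <- outer(memb, memb, "==")
  sum((W - outer(s, s) / m2) * same) / m2
}

# shared wrapper turning an igraph communities object into a partition
# whose reported Q comes from the package's own modularity formula
.as_partition <- function(net, comm, method, seed) {
  memb <- stats::setNames(igraph::membership(comm), igraph::V(net)$name)
  part <- new_partition(memb, method = method, seed = seed)
  part$modularity <- modularity_value(net, part$membership)
  part
}

#' Louvain community detection
#'
#' Two-phase greedy weighted-modularity optimization: each node is moved
#' to the neighbouring community with the largest modularity gain, then
#' communities are merged into super-nodes and the procedure repeats. The
#' node visiting order is shuffled by the seed, so the seed is part of the
#' result's identity. The reported modularity is recomputed with
#' [modularity_value()] on the returned membership.
#'
#' @param net an undirected weighted `igraph` network.
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed.
#' @return a `partition`.
#' @export
louvain_communities <- function(net, resolution = 1, seed = 1L) {
  net <- ensure_names(net)
  if (igraph::ecount(net) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(net)),
                            igraph::V(net)$name)
    return(new_partition(memb, method = "louvain", seed = seed))
  }
  set.seed(seed)
  comm <- igraph::cluster_louvain(net, weights = igraph::E(net)$weight,
                                  resolution = resolution)
  .as_partition(net, comm, "louvain", seed)
}

#' Map-equation (InfoMap) community detection
#'
#' Minimizes the two-level map equation - the expected description length
#' of a random walker's movements when walks are coded with one codebook
#' per module plus an index codebook - for the stationary walk on the
#' weighted graph (stationary probability proportional to strength on
#' undirected graphs). Isolates become singleton modules. The achieved
#' description length is reported alongside the membership, and the
#' modularity of the returned membership is recomputed with
#' [modularity_value()].
#'
#' @param net an undirected weighted `igraph` network.
#' @param seed integer seed.
#' @return a `partition` with extra element `codelength` (bits).
#' @export
infomap_communities <- function(net, seed = 1L) {
  net <- ensure_names(net)
  if (igraph::ecount(net) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(net)),
                            igraph::V(net)$name)
    return(new_partition(memb, method = "infomap", seed = seed))
  }
  set.seed(seed)
  comm <- igraph::cluster_infomap(net, e.weights = igraph::E(net)$weight)
  part <- .as_partition(net, comm, "infomap", seed)
  part$codelength <- map_equation(net, part$membership)
  part
}

#' Evaluate the two-level map equation
#'
#' Computes `L(M) = q * H(Q) + sum_i p_i * H(P_i)` in bits for a given
#' membership: the module-switch rate times the index-codebook entropy,
#' plus each module's visit rate times its within-module codebook entropy.
#' Node visit probabilities are proportional to strength; module exit
#' probabilities to the weight leaving the module. Independent of the
#' optimizer, so it can rank candidate partitions.
#'
#' @param net an undirected weighted `igraph` network.
#' @param membership named community labels covering all nodes.
#' @return description length in bits per step.
#' @export
map_equation <- function(net, membership) {
  W <- weighted_adjacency(ensure_names(net))
  m2 <- sum(W)
  if (m2 == 0) return(NA_real_)
  memb <- membership[rownames(W)]
  p <- rowSums(W) / m2
  mods <- unique(memb)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  q_i <- vapply(mods, function(g) {
    inside <- memb == g
    sum(W[inside, !inside, drop = FALSE]) / m2
  }, numeric(1))
  q <- sum(q_i)
  HQ <- if (q > 0) -sum(plogp(q_i / q)) else 0
  within <- vapply(seq_along(mods), function(k) {
    inside <- memb == mods[k]
    tot <- q_i[k] + sum(p[inside])
    if (tot == 0) return(0)
    tot * (-sum(plogp(p[inside] / tot)) - plogp(q_i[k] / tot))
  }, numeric(1))
  q * HQ + sum(within)
}

#' Subcluster each community independently
#'
#' Runs the chosen community-detection method on every induced community
#' subgraph, giving one sub-partition per parent community. Subclustering
#' never crosses parent boundaries; single-node communities yield trivial
#' partitions.
#'
#' @param net an undirected weighted `igraph` network.
#' @param part parent `partition`.
#' @param method `"louvain"` or `"infomap"`.
#' @param seed integer seed.
#' @return named list: community label -> `partition` on that subgraph.
#' @export
subcluster <- function(net, part, method = c("louvain", "infomap"),
                       seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(part, "partition"))
  net <- ensure_names(net)
  memb <- part$membership[igraph::V(net)$name]
  if (anyNA(memb)) stop_named("partition does not cover all network nodes")
  out <- list()
  for (g in sort(unique(memb))) {
    sub <- igraph::induced_subgraph(net, which(memb == g))
    out[[as.character(g)]] <- switch(method,
      louvain = louvain_communities(sub, seed = derive_seed(seed, paste0("sub", g))),
      infomap = infomap_communities(sub, seed = derive_seed(seed, paste0("sub", g))))
  }
  out
}

# contingency table of two aligned partitions
.pair_table <- function(p1, p2) {
  n1 <- p1$membership
  n2 <- p2$membership[names(n1)]
  if (anyNA(n2) || length(p2$membership) != length(n1))
    stop_named("partitions are defined on different node sets")
  table(n1, n2)
}

#' Rand index
#'
#' The fraction of unordered node pairs on which two partitions agree
#' (joined in both or separated in both): `(a + d) / C(n, 2)`.
#'
#' @param p1,p2 `partition` objects on the same node set.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(p1, p2) {
  tab <- .pair_table(p1, p2)
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  cc <- sum(choose(colSums(tab), 2)) - a
  d <- choose(n, 2) - a - b - cc
  (a + d) / choose(n, 2)
}

#' Adjusted Rand index
#'
#' Chance-corrected variant of the Rand index: 0 expected for independent
#' partitions, 1 for identical ones.
#'
#' @param p1,p2 `partition` objects on the same node set.
#' @return adjusted Rand index (can be slightly negative).
#' @export
adjusted_rand_index <- function(p1, p2) {
  tab <- .pair_table(p1, p2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Variation of information
#'
#' Information-theoretic partition distance `H(p1) + H(p2) - 2 I(p1; p2)`
#' in nats; 0 for identical partitions.
#'
#' @param p1,p2 `partition` objects on the same node set.
#' @return variation of information in nats (>= 0).
#' @export
variation_of_information <- function(p1, p2) {
  tab <- .pair_table(p1, p2)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  H <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  I <- sum(ifelse(pxy > 0, pxy * log(pxy / outer(px, py)), 0))
  max(0, H(px) + H(py) - 2 * I)
}

#' Contract communities into a multigraph of clusters
#'
#' Collapses every community into one node (anchored at its
#' strongest-by-weight member, whose name the cluster node inherits) while
#' keeping every inter-cluster edge individually, so parallel edges show
#' how densely two clusters interrelate. Intra-cluster edges are dropped.
#' The inter-cluster edge multiset, and hence the total cross-edge weight,
#' is preserved exactly.
#'
#' @param net an undirected weighted `igraph` network.
#' @param part a `partition` of the network.
#' @return an undirected multigraph with one node per community and vertex
#'   attributes `anchor` (strongest member) and `cluster_size`.
#' @export
contract_clusters <- function(net, part) {
  stopifnot(inherits(part, "partition"))
  net <- ensure_names(net)
  memb <- part$membership[igraph::V(net)$name]
  if (anyNA(memb)) stop_named("partition does not cover all network nodes")
  s <- node_strength(net)
  anchors <- vapply(sort(unique(memb)), function(g) {
    nodes <- names(memb)[memb == g]
    nodes[which.max(s[nodes])]
  }, character(1))
  g <- igraph::contract(net, mapping = memb,
                        vertex.attr.comb = list(name = "ignore", "ignore"))
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  igraph::V(g)$name <- anchors
  igraph::V(g)$anchor <- anchors
  igraph::V(g)$cluster_size <- as.integer(table(memb))
  g
}
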