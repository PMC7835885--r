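# Permutation-based significance for network statistics (CUG tests,
# QAP/gcor) and the two-network comparison.

new_permutation_test <- function(observed, draws, mode, R, seed) {
  structure(list(observed = observed, null_draws = draws,
                 p_greater = (1 + sum(draws >= observed)) / (R + 1),
                 p_lower = (1 + sum(draws <= observed)) / (R + 1),
                 mode = mode, R = R, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test (%s, R = %d): observed = %.4g, p_greater = %.4g, p_lower = %.4g\n",
              x$mode, x$R, x$observed, x$p_greater, x$p_lower))
  invisible(x)
}

#' Conditional uniform graph (CUG) test
#'
#' Monte-Carlo test of whether an observed graph-level statistic could
#' arise in a random graph conditioned on size (each possible edge present
#' with probability 1/2) or on the observed edge count (uniform over
#' graphs with that many edges; for undirected graphs conditioning on the
#' dyad census is equivalent). The observed graph is binarized - weights
#' are ignored, since uniform conditioning is ill-posed for continuous
#' weights. Draws on which the statistic is undefined are resampled and
#' counted. Both tail p-values use add-one smoothing, so they are never
#' exactly zero.
#'
#' @param net an undirected `igraph` network.
#' @param statistic function taking a binary undirected `igraph` and
#'   returning one number.
#' @param mode conditioning: `"size"`, `"edges"`, or `"dyad_census"`.
#' @param R number of random draws (>= 99).
#' @param seed integer seed.
#' @return a `permutation_test` with extra element `resampled` (count of
#'   undefined draws).
#' @export
cug_test <- function(net, statistic, mode = c("size", "edges", "dyad_census"),
                     R = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(R >= 99)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  gbin <- net
  if ("weight" %in% igraph::edge_attr_names(gbin))
    gbin <- igraph::delete_edge_attr(gbin, "weight")
  obs <- statistic(gbin)
  if (!is.finite(obs)) stop_named("statistic undefined on the observed graph")
  set.seed(seed)
  draws <- numeric(R)
  resampled <- 0L
  for (r in seq_len(R)) {
    repeat {
      g <- if (mode == "size") igraph::sample_gnp(n, 0.5, directed = FALSE)
           else igraph::sample_gnm(n, m, directed = FALSE)
      val <- tryCatch(statistic(g), error = function(e) NA_real_)
      if (is.finite(val)) break
      resampled <- resampled + 1L
    }
    draws[r] <- val
  }
  out <- new_permutation_test(obs, draws, mode, R, seed)
  out$resampled <- resampled
  out
}

#' Graph correlation (gcor)
#'
#' Pearson correlation of the strictly-upper-triangle entries of two
#' weighted adjacency matrices aligned on their shared nodes; a pair
#' without an edge contributes 0, so the measure captures both edge
#' presence and strength. `binary = TRUE` correlates edge indicators
#' instead.
#'
#' @param net1,net2 undirected weighted `igraph` networks with node names.
#' @param aligned_ids node ids to align on; default, the shared names.
#' @param binary correlate binarized adjacencies.
#' @return correlation in `[-1, 1]`.
#' @export
gcor <- function(net1, net2, aligned_ids = NULL, binary = FALSE) {
  if (is.null(aligned_ids))
    aligned_ids <- intersect(igraph::V(net1)$name, igraph::V(net2)$name)
  if (length(aligned_ids) < 3)
    stop_named("gcor requires at least 3 shared nodes")
  A1 <- weighted_adjacency(shared_subgraph(net1, aligned_ids))[aligned_ids, aligned_ids]
  A2 <- weighted_adjacency(shared_subgraph(net2, aligned_ids))[aligned_ids, aligned_ids]
  if (binary) { A1 <- (A1 > 0) * 1; A2 <- (A2 > 0) * 1 }
  x <- A1[upper.tri(A1)]
  y <- A2[upper.tri(A2)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_named("gcor undefined: zero variance in an adjacency triangle")
  stats::cor(x, y)
}

#' Quadratic assignment procedure (QAP) test
#'
#' Permutation test of the graph correlation between two networks: each
#' null draw relabels the second network's nodes by one random permutation
#' applied simultaneously to the rows and columns of its adjacency, which
#' preserves the graph structure while destroying the node alignment. The
#' one-sided `p_greater` is the headline value; the full null distribution
#' is retained for plotting.
#'
#' @param net1,net2 undirected weighted `igraph` networks with node names.
#' @param aligned_ids node ids to align on; default, the shared names.
#' @param R number of permutations (>= 99).
#' @param seed integer seed.
#' @param binary correlate binarized adjacencies.
#' @return a `permutation_test`.
#' @export
qap_test <- function(net1, net2, aligned_ids = NULL, R = 1000L, seed = 1L,
                     binary = FALSE) {
  stopifnot(R >= 99)
  if (is.null(aligned_ids))
    aligned_ids <- intersect(igraph::V(net1)$name, igraph::V(net2)$name)
  if (length(aligned_ids) < 3)
    stop_named("QAP requires at least 3 shared nodes")
  A1 <- weighted_adjacency(shared_subgraph(net1, aligned_ids))[aligned_ids, aligned_ids]
  A2 <- weighted_adjacency(shared_subgraph(net2, aligned_ids))[aligned_ids, aligned_ids]
  if (binary) { A1 <- (A1 > 0) * 1; A2 <- (A2 > 0) * 1 }
  x <- A1[upper.tri(A1)]
  tri_cor <- function(B) {
    y <- B[upper.tri(B)]
    if (stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  if (stats::sd(x) == 0)
    stop_named("QAP undefined: zero variance in an adjacency triangle")
  obs <- tri_cor(A2)
  if (is.na(obs))
    stop_named("QAP undefined: zero variance in an adjacency triangle")
  set.seed(seed)
  k <- length(aligned_ids)
  draws <- vapply(seq_len(R), function(r) {
    perm <- sample.int(k)
    tri_cor(A2[perm, perm])
  }, numeric(1))
  new_permutation_test(obs, draws, "qap", R, seed)
}

#' Induced subgraph on a set of node ids
#'
#' @param net an undirected `igraph` network.
#' @param ids node names; must all exist in the network.
#' @return the induced subgraph with edges and attributes preserved.
#' @export
shared_subgraph <- function(net, ids) {
  unknown <- setdiff(ids, igraph::V(net)$name)
  if (length(unknown))
    stop_named("unknown node id(s): %s", paste(unknown, collapse = ", "))
  igraph::induced_subgraph(net, ids)
}

# Spearman rho and p for two aligned numeric vectors.
.spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  list(rho = rho, p = spearman_pvalue(rho, n), n = n)
}

#' Compare two physiological networks
#'
#' Over the shared nodes, correlates (Spearman) node strength,
#' eigencentrality, and flow betweenness computed on each full network;
#' over the shared edges, correlates edge weights; computes the graph
#' correlation and QAP test on the shared-node subgraphs; and, when
#' clusterings are supplied, reports their Rand index and variation of
#' information restricted to shared nodes.
#'
#' @param net1,net2 undirected weighted `igraph` networks with node names.
#' @param clusterings optional list of two `partition` objects.
#' @param R permutations for the QAP test.
#' @param seed integer seed.
#' @return an object of class `network_comparison`.
#' @export
compare_networks <- function(net1, net2, clusterings = NULL, R = 1000L,
                             seed = 1L) {
  shared <- intersect(igraph::V(net1)$name, igraph::V(net2)$name)
  if (length(shared) < 3)
    stop_named("networks share fewer than 3 nodes")
  s1 <- node_strength(net1)[shared]; s2 <- node_strength(net2)[shared]
  e1 <- eigencentrality(net1)[shared]; e2 <- eigencentrality(net2)[shared]
  f1 <- flow_betweenness(net1)[shared]; f2 <- flow_betweenness(net2)[shared]

  el1 <- igraph::as_edgelist(net1)
  key1 <- paste(pmin(el1[, 1], el1[, 2]), pmax(el1[, 1], el1[, 2]), sep = "|")
  el2 <- igraph::as_edgelist(net2)
  key2 <- paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2]), sep = "|")
  both <- intersect(key1, key2)
  edge_cor <- if (length(both) < 3) list(rho = NA_real_, p = NA_real_,
                                         n = length(both))
              else .spearman_pair(igraph::E(net1)$weight[match(both, key1)],
                                  igraph::E(net2)$weight[match(both, key2)])

  g1 <- shared_subgraph(net1, shared)
  g2 <- shared_subgraph(net2, shared)
  gc <- tryCatch(gcor(g1, g2, shared), error = function(e) NA_real_)
  qp <- tryCatch(qap_test(g1, g2, shared, R = R, seed = seed),
                 error = function(e) NULL)
  agreement <- NULL
  if (!is.null(clusterings)) {
    sub_part <- function(p) new_partition(p$membership[shared],
                                          method = p$method, seed = p$seed)
    p1 <- sub_part(clusterings[[1]]); p2 <- sub_part(clusterings[[2]])
    agreement <- list(rand = rand_index(p1, p2),
                      vi = variation_of_information(p1, p2))
  }
  structure(list(
    shared_nodes = shared,
    shared_edges = both,
    node_strength = .spearman_pair(s1, s2),
    eigencentrality = .spearman_pair(e1, e2),
    flow_betweenness = .spearman_pair(f1, f2),
    edge_weight = edge_cor,
    gcor = gc, qap = qp, cluster_agreement = agreement),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network comparison over %d shared nodes, %d shared edges\n",
              length(x$shared_nodes), length(x$shared_edges)))
  cat(sprintf("  strength rho = %.3f, eigencentrality rho = %.3f, flow betweenness rho = %.3f\n",
              x$node_strength$rho, x$eigencentrality$rho,
              x$flow_betweenness$rho))
  cat(sprintf("  edge weight rho = %.3f, gcor = %.3f, QAP p_greater = %s\n",
              x$edge_weight$rho, x$gcor,
              if (is.null(x$qap)) "NA" else format(x$qap$p_greater)))
  invisible(x)
}
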