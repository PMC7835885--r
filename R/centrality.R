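# Centrality suite: eigencentrality, Freeman flow betweenness, edge
# betweenness, Freeman centralization, and centrality assortativity.

#' Eigencentrality
#'
#' Leading eigenvector of the weighted adjacency matrix, the radial
#' influence measure of the network: a node is central in proportion to
#' the summed centrality of its neighbours. Computed by shifted power
#' iteration (the shift guards against oscillation on bipartite graphs) to
#' relative tolerance 1e-10, with the nonnegative Perron orientation, and
#' rescaled so the maximum is 1. On disconnected graphs mass concentrates
#' on the component with the largest leading eigenvalue.
#'
#' @param net an undirected weighted `igraph` network.
#' @return named numeric vector in `[0, 1]`.
#' @export
eigencentrality <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    warn_named("network has no edges; eigencentrality is all zero")
    return(stats::setNames(rep(0, n), nm))
  }
  W <- weighted_adjacency(net)
  shift <- max(rowSums(W))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(100000L)) {
    v_new <- W %*% v + shift * v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < 1e-10 * max(abs(v_new))) { v <- v_new; break }
    v <- v_new
  }
  v <- abs(as.numeric(v))
  stats::setNames(v / max(v), nm)
}

# Gusfield flow-equivalent tree: all-pairs max-flow values from n - 1
# max-flow computations. Works on disconnected graphs (cross-component
# flow is 0).
all_pairs_maxflow <- function(net, capacity = igraph::E(net)$weight) {
  n <- igraph::vcount(net)
  M <- matrix(0, n, n)
  if (n < 2 || igraph::ecount(net) == 0) return(M)
  if (is.null(capacity)) capacity <- rep(1, igraph::ecount(net))
  parent <- rep(1L, n)
  fl <- rep(0, n)
  for (i in 2:n) {
    t <- parent[i]
    mf <- igraph::max_flow(net, source = i, target = t, capacity = capacity)
    fl[i] <- mf$value
    side <- rep(FALSE, n)
    side[as.integer(mf$partition1)] <- TRUE
    if (!side[i]) side <- !side
    js <- which(seq_len(n) > i & parent == t & side)
    parent[js] <- i
  }
  # min tree edge along the path between each pair
  adj <- vector("list", n)
  for (i in 2:n) {
    adj[[i]] <- rbind(adj[[i]], c(parent[i], fl[i]))
    adj[[parent[i]]] <- rbind(adj[[parent[i]]], c(i, fl[i]))
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    stack <- list(c(s, Inf))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      u <- cur[1]; mn <- cur[2]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (seen[v]) next
        seen[v] <- TRUE
        m2 <- min(mn, nb[r, 2])
        M[s, v] <- m2
        stack[[length(stack) + 1L]] <- c(v, m2)
      }
    }
  }
  M
}

#' Freeman flow betweenness
#'
#' The medial (gatekeeping) centrality: for each node, the total max-flow
#' between all other pairs that is lost when the node is removed, with
#' edge capacities equal to the edge weights:
#' `f(i) = sum over pairs j < k (both != i) of maxflow(j,k) - maxflow
#' without i(j,k)`. Raw (unnormalized) values are returned by default;
#' `normalize = TRUE` divides by the total flow between pairs excluding
#' the node. Deterministic; isolates score 0.
#'
#' @param net an undirected weighted `igraph` network.
#' @param normalize divide by total pairwise flow excluding each node.
#' @return named numeric vector of nonnegative values.
#' @export
flow_betweenness <- function(net, normalize = FALSE) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (n < 3) return(stats::setNames(rep(0, n), nm))
  cap <- igraph::E(net)$weight
  if (is.null(cap)) cap <- rep(1, igraph::ecount(net))
  M <- all_pairs_maxflow(net, cap)
  f <- numeric(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    gi <- igraph::delete_vertices(net, i)
    capi <- igraph::E(gi)$weight
    Mi <- all_pairs_maxflow(gi, capi)
    with_i <- sum(M[keep, keep][upper.tri(Mi)])
    without_i <- sum(Mi[upper.tri(Mi)])
    f[i] <- with_i - without_i
    if (normalize && with_i > 0) f[i] <- f[i] / with_i
  }
  stats::setNames(pmax(f, 0), nm)
}

#' Unweighted shortest-path edge betweenness
#'
#' The number of shortest paths that pass through each link, counted over
#' unordered node pairs with fractional credit when several shortest paths
#' tie. Paths are hop-count (unweighted) paths.
#'
#' @param net an undirected `igraph` network.
#' @return numeric vector, one value per edge, named `"a|b"`.
#' @export
edge_path_betweenness <- function(net) {
  eb <- igraph::edge_betweenness(net, weights = NA, directed = FALSE)
  el <- igraph::as_edgelist(net)
  stats::setNames(eb, paste(el[, 1], el[, 2], sep = "|"))
}

#' Freeman centralization of a centrality vector
#'
#' `sum(c_max - c_i) / ((n - 1) * c_max)`: the relative concentration of a
#' centrality in few nodes, 0 for an all-equal vector and 1 when a single
#' node holds everything. Defined as 0 when the maximum is 0.
#'
#' @param cv numeric centrality vector (length >= 2).
#' @return centralization in `[0, 1]`.
#' @export
freeman_centralization <- function(cv) {
  stopifnot(length(cv) >= 2)
  cmax <- max(cv)
  if (cmax == 0) return(0)
  sum(cmax - cv) / ((length(cv) - 1) * cmax)
}

#' Assortativity of a node centrality
#'
#' Pearson correlation of endpoint centrality values over the edge list,
#' with each undirected edge counted in both orientations (the Newman
#' continuous-attribute convention): positive when nodes of similar
#' centrality link together.
#'
#' @param net an undirected `igraph` network.
#' @param cv named numeric centrality vector covering all nodes.
#' @return correlation in `[-1, 1]`.
#' @export
centrality_assortativity <- function(net, cv) {
  if (igraph::ecount(net) < 2)
    stop_named("assortativity requires at least 2 edges")
  el <- igraph::as_edgelist(net)
  x <- cv[el[, 1]]
  y <- cv[el[, 2]]
  if (stats::sd(c(x, y)) == 0)
    stop_named("assortativity undefined: zero centrality variance over edges")
  stats::cor(c(x, y), c(y, x))
}
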