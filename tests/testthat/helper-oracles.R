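# Independent brute-force oracles and small graph fixtures, built in code.

# Spearman rho via explicit ranking then the covariance / deviation ratio.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Weighted modularity via the per-community formulation
# sum_c [ w_in_c / 2m - (s_c / 2m)^2 ], coded independently of the package.
oracle_modularity <- function(g, memb) {
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  m2 <- sum(W)
  s <- rowSums(W)
  sum(vapply(unique(memb), function(cl) {
    inside <- memb == cl
    sum(W[inside, inside]) / m2 - (sum(s[inside]) / m2)^2
  }, numeric(1)))
}

# All set partitions of n elements as restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(), 0L)
  out
}

# Freeman flow betweenness by independent per-pair max-flow and deletion.
oracle_flowbet <- function(g) {
  n <- igraph::vcount(g)
  cap <- igraph::E(g)$weight
  f <- numeric(n)
  for (i in seq_len(n)) {
    gi <- igraph::delete_vertices(g, i)
    capi <- igraph::E(gi)$weight
    others <- setdiff(seq_len(n), i)
    for (a in seq_along(others)[-length(others)]) {
      for (b in (a + 1):length(others)) {
        j <- others[a]; k <- others[b]
        with_i <- igraph::max_flow(g, j, k, capacity = cap)$value
        without <- igraph::max_flow(gi, a, b, capacity = capi)$value
        f[i] <- f[i] + with_i - without
      }
    }
  }
  stats::setNames(f, igraph::V(g)$name)
}

# Unweighted local clustering by exhaustive triangle enumeration.
oracle_local_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(NA_real_)
    tri <- 0
    for (a in seq_along(nb)[-length(nb)])
      for (b in (a + 1):length(nb))
        if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    tri / choose(length(nb), 2)
  }, numeric(1))
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) D[el[r, 1], el[r, 2]] <- D[el[r, 2], el[r, 1]] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# --- fixtures --------------------------------------------------------

unit_weights <- function(g) {
  igraph::E(g)$weight <- 1
  g
}

two_k4_bridge <- function() {
  unit_weights(igraph::graph_from_literal(
    a - b, a - c, a - d, b - c, b - d, c - d,
    e - f, e - g, e - h, f - g, f - h, g - h, d - e))
}

unit_star <- function(m) {
  g <- igraph::make_star(m + 1, mode = "undirected")
  igraph::V(g)$name <- c("hub", paste0("l", seq_len(m)))
  unit_weights(g)
}

unit_path <- function(labels = c("a", "b", "c")) {
  g <- igraph::make_ring(length(labels), circular = FALSE)
  igraph::V(g)$name <- labels
  unit_weights(g)
}

random_weighted_graph <- function(n, m, seed) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- stats::runif(m, 0.1, 1)
  g
}

# small correlation_result built from an explicit p/rho matrix
corr_from_matrices <- function(rho, p, n_obs = 100L) {
  vars <- colnames(rho)
  structure(list(rho = rho, rho2 = rho^2, p = p,
                 n_obs = matrix(n_obs, nrow(rho), ncol(rho),
                                dimnames = dimnames(rho)),
                 variables = vars),
            class = "correlation_result")
}
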