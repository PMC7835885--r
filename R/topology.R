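# Topology metric panel: density, Krackhardt connectedness and efficiency,
# characteristic path length, Barrat weighted clustering, small-world
# indices, scale-free fit, and node strength.

#' Network density
#'
#' Edges divided by the number of unordered node pairs.
#'
#' @param net an undirected `igraph` network.
#' @return density in `[0, 1]`.
#' @export
net_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop_named("density undefined for fewer than 2 nodes")
  igraph::ecount(net) / n_pairs(n)
}

#' Krackhardt connectedness
#'
#' The fraction of unordered node pairs joined by some path. A connected
#' graph scores 1; each isolate removes its `n - 1` pairs from the
#' numerator.
#'
#' @param net an undirected `igraph` network.
#' @return connectedness in `[0, 1]`.
#' @export
net_connectedness <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop_named("connectedness undefined for fewer than 2 nodes")
  comp <- igraph::components(net)
  reachable <- sum(n_pairs(comp$csize))
  reachable / n_pairs(n)
}

#' Krackhardt efficiency
#'
#' One minus the fraction of edges that are redundant beyond a spanning
#' structure: `1 - (e - (n - c)) / (C(n,2) - (n - c))` with `c` the number
#' of connected components. Any forest scores 1 (zero redundancy); a
#' complete graph scores 0. Clipped to `[0, 1]`; a zero denominator is
#' defined as 1.
#'
#' @param net an undirected `igraph` network.
#' @return efficiency in `[0, 1]`.
#' @export
net_efficiency <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop_named("efficiency undefined for fewer than 2 nodes")
  comp <- igraph::components(net)$no
  span <- n - comp
  denom <- n_pairs(n) - span
  if (denom <= 0) return(1)
  min(1, max(0, 1 - (igraph::ecount(net) - span) / denom))
}

#' Characteristic path length
#'
#' Mean unweighted (hop-count) shortest-path length over reachable
#' unordered pairs; unreachable pairs (and hence isolates) are excluded
#' rather than treated as infinite.
#'
#' @param net an undirected `igraph` network.
#' @return mean shortest-path length in hops.
#' @export
char_path_length <- function(net) {
  D <- igraph::distances(net, weights = NA)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) stop_named("no reachable node pairs")
  mean(d)
}

# Barrat weighted local clustering coefficient per node; NA for degree < 2.
barrat_local <- function(net) {
  W <- weighted_adjacency(net)
  A <- (W > 0) * 1
  k <- rowSums(A)
  s <- rowSums(W)
  n <- nrow(W)
  cc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] > 0)
    tot <- 0
    for (a in seq_along(nb)[-length(nb)]) {
      for (b in (a + 1):length(nb)) {
        j <- nb[a]; h <- nb[b]
        if (A[j, h] > 0) tot <- tot + W[i, j] + W[i, h]
      }
    }
    cc[i] <- tot / (s[i] * (k[i] - 1))
  }
  stats::setNames(cc, igraph::V(net)$name)
}

#' Barrat weighted transitivity and clustering coefficient
#'
#' Computes the Barrat weighted local clustering coefficient
#' `c_i = 1 / (s_i (k_i - 1)) * sum over triangles at i of (w_ij + w_ih)/2`
#' and aggregates it two ways: `T` is the mean weighted by `k_i (k_i - 1)`
#' (the weighted analogue of global transitivity) and `CC` is the plain
#' mean. Nodes of degree < 2 are excluded from both means. With unit
#' weights both collapse to their unweighted counterparts.
#'
#' @param net an undirected weighted `igraph` network.
#' @return list with elements `T`, `CC`, and `local` (per-node vector).
#' @export
clustering_metrics <- function(net) {
  if (igraph::vcount(net) < 3)
    stop_named("clustering undefined for fewer than 3 nodes")
  cc <- barrat_local(net)
  k <- igraph::degree(net)
  ok <- !is.na(cc)
  if (!any(ok)) stop_named("no node with degree >= 2")
  w <- k[ok] * (k[ok] - 1)
  list(T = sum(w * cc[ok]) / sum(w), CC = mean(cc[ok]), local = cc)
}

#' Small-world index and smallworldness
#'
#' Both compare the clustering-to-path-length ratio of the network's main
#' component against random-graph baselines with the same size and mean
#' degree. `SWI` uses analytic baselines `C_rand = kbar / n` and
#' `L_rand = ln(n) / ln(kbar)`; `smallworldness` (the Humphries-Gurney
#' sigma) replaces them with averages over `B` seeded Erdos-Renyi graphs
#' with identical node and edge counts. Clustering is the unweighted global
#' transitivity. Requires a main component with mean degree above 1.
#'
#' @param net an undirected `igraph` network.
#' @param B number of random baseline graphs (0 skips `smallworldness`).
#' @param seed integer seed for the baseline draws.
#' @return list with `SWI`, `smallworldness`, `C`, `L`, `C_rand`, `L_rand`.
#' @export
small_world <- function(net, B = 100L, seed = 1L) {
  comp <- igraph::components(net)
  main <- igraph::induced_subgraph(net, which(comp$membership ==
                                              which.max(comp$csize)))
  n <- igraph::vcount(main)
  m <- igraph::ecount(main)
  kbar <- 2 * m / n
  if (kbar <= 1) stop_named("mean degree <= 1; small-world index undefined")
  C <- igraph::transitivity(main, type = "global")
  L <- char_path_length(main)
  C_rand <- kbar / n
  L_rand <- log(n) / log(kbar)
  swi <- (C / C_rand) / (L / L_rand)
  sigma <- NA_real_
  Cr <- Lr <- NA_real_
  if (B > 0) {
    set.seed(seed)
    cs <- ls <- numeric(B)
    for (b in seq_len(B)) {
      r <- igraph::sample_gnm(n, m, directed = FALSE)
      cs[b] <- igraph::transitivity(r, type = "global")
      ls[b] <- char_path_length(r)
    }
    Cr <- mean(cs, na.rm = TRUE)
    Lr <- mean(ls, na.rm = TRUE)
    sigma <- (C / Cr) / (L / Lr)
  }
  list(SWI = swi, smallworldness = sigma, C = C, L = L,
       C_rand = if (B > 0) Cr else C_rand, L_rand = if (B > 0) Lr else L_rand)
}

#' Scale-free fitting index
#'
#' Bins node degrees into `nbins` equal-width bins, takes the mean degree
#' and empirical frequency of each nonempty bin, and fits an ordinary
#' least-squares line to log10 frequency versus log10 mean degree. The R
#' squared of that fit is the scale-free fitting index; a negative slope
#' indicates the decaying power-law shape. Degree-zero nodes are excluded
#' (their log is undefined). At least 2 nonempty bins are required, so
#' regular graphs are rejected.
#'
#' @param net an undirected `igraph` network.
#' @param nbins number of equal-width degree bins (default 10).
#' @return list with `R2`, `slope`, and the per-bin data frame `bins`.
#' @export
scale_free_fit <- function(net, nbins = 10L) {
  d <- igraph::degree(net)
  d <- d[d > 0]
  if (length(unique(d)) < 2)
    stop_named("scale-free fit undefined: fewer than 2 nonempty degree bins")
  br <- seq(min(d), max(d), length.out = nbins + 1)
  bin <- cut(d, breaks = br, include.lowest = TRUE)
  dk <- tapply(d, bin, mean)
  ct <- tapply(d, bin, length)
  keep <- !is.na(dk)
  dk <- dk[keep]; ct <- ct[keep]
  if (length(dk) < 2)
    stop_named("scale-free fit undefined: fewer than 2 nonempty degree bins")
  freq <- ct / sum(ct)
  fit <- stats::lm(log10(freq) ~ log10(dk))
  list(R2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]),
       bins = data.frame(mean_degree = as.numeric(dk),
                         frequency = as.numeric(freq)))
}

#' Node strength
#'
#' Sum of incident edge weights per node; isolates score 0.
#'
#' @param net an undirected weighted `igraph` network.
#' @return named numeric vector.
#' @export
node_strength <- function(net) {
  if (igraph::ecount(net) == 0)
    return(stats::setNames(rep(0, igraph::vcount(net)), igraph::V(net)$name))
  igraph::strength(net, weights = igraph::E(net)$weight)
}

#' Full topology summary panel
#'
#' Computes the complete per-network record: size, edges, density,
#' efficiency, connectedness, characteristic path length, Barrat weighted
#' transitivity and clustering coefficient, small-world index and
#' smallworldness, eigencentrality and flow betweenness centralizations
#' and assortativities, and the scale-free fitting index. Fields whose
#' preconditions fail (e.g. the scale-free fit on a regular graph) are
#' reported as `NA`.
#'
#' @param net an undirected weighted `igraph` network.
#' @param B random baselines for `smallworldness` (default 100).
#' @param seed integer seed.
#' @param flow if `FALSE`, skip the (costlier) flow betweenness fields.
#' @return a one-row data frame.
#' @export
topology_summary <- function(net, B = 100L, seed = 1L, flow = TRUE) {
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  tc <- tryCatch(clustering_metrics(net),
                 error = function(e) list(T = NA_real_, CC = NA_real_))
  sw <- tryCatch(small_world(net, B = B, seed = seed),
                 error = function(e) list(SWI = NA_real_,
                                          smallworldness = NA_real_))
  ev <- tryCatch(eigencentrality(net), error = function(e) NULL)
  out <- data.frame(
    size = igraph::vcount(net),
    edges = igraph::ecount(net),
    density = try_na(net_density(net)),
    efficiency = try_na(net_efficiency(net)),
    connectedness = try_na(net_connectedness(net)),
    L = try_na(char_path_length(net)),
    T = tc$T, CC = tc$CC,
    SWI = sw$SWI, smallworldness = sw$smallworldness,
    eigencentrality_centralization =
      if (is.null(ev)) NA_real_ else try_na(freeman_centralization(ev)),
    eigencentrality_assortativity =
      if (is.null(ev)) NA_real_
      else try_na(centrality_assortativity(net, ev)),
    scale_free_R2 = try_na(scale_free_fit(net)$R2))
  if (flow) {
    fb <- tryCatch(flow_betweenness(net), error = function(e) NULL)
    out$flow_betweenness_centralization <-
      if (is.null(fb)) NA_real_ else try_na(freeman_centralization(fb))
    out$flow_betweenness_assortativity <-
      if (is.null(fb)) NA_real_
      else try_na(centrality_assortativity(net, fb))
  } else {
    out$flow_betweenness_centralization <- NA_real_
    out$flow_betweenness_assortativity <- NA_real_
  }
  out
}
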