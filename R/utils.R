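# Internal helpers shared across the pipeline.

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage (simulation, Louvain sweeps, permutation tests,
#' layouts, attacks) draws its own seed deterministically from one master
#' seed plus a stage name, so a single integer reproduces a whole run.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) + 97 * h) %% 2147483647)
}

# Unordered node pairs n*(n-1)/2, vectorized and guarded for n < 2.
n_pairs <- function(n) ifelse(n < 2, 0, n * (n - 1) / 2)

# weighted adjacency (rho^2) of a physiological network, nodes in vertex order
weighted_adjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE))
}

# give unnamed graphs canonical "1".."n" vertex names
ensure_names <- function(net) {
  if (is.null(igraph::V(net)$name))
    net <- igraph::set_vertex_attr(net, "name",
                                   value = as.character(seq_len(igraph::vcount(net))))
  net
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_named <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
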