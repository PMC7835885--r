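# File formats: cohort CSV with metadata sidecar, edge-list CSV, GraphML.

#' Write a cohort table to CSV
#'
#' Writes the value matrix (header = variable short names) and a metadata
#' sidecar CSV with columns `id,short_name,category,units`.
#'
#' @param table a `cohort_table`.
#' @param path path of the values CSV.
#' @param meta_path path of the metadata sidecar; default
#'   `<path>` with `_meta.csv` suffix.
#' @return invisibly, the two paths.
#' @export
write_cohort_csv <- function(table, path,
                             meta_path = sub("\\.csv$", "_meta.csv", path)) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(as.data.frame(table$values), path, row.names = FALSE)
  utils::write.csv(table$meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a cohort table from CSV
#'
#' @param path values CSV (one row per subject, one column per variable).
#' @param meta_path metadata sidecar CSV; if absent, minimal metadata is
#'   synthesized from the header.
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path,
                            meta_path = sub("\\.csv$", "_meta.csv", path)) {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  storage.mode(values) <- "double"
  meta <- if (file.exists(meta_path)) utils::read.csv(meta_path)
          else data.frame(id = seq_len(ncol(values)),
                          short_name = colnames(values),
                          category = "Unknown", units = "")
  cohort_table(values, meta)
}

#' Write a network edge list to CSV
#'
#' Columns: `source`, `target`, `rho`, `rho2`, `p`, `n_obs`.
#'
#' @param net a physiological network (undirected `igraph`).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   rho = igraph::E(net)$rho,
                   rho2 = igraph::E(net)$weight,
                   p = igraph::E(net)$p,
                   n_obs = igraph::E(net)$n_obs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a network to GraphML
#'
#' GraphML is the canonical attribute-rich interchange format here: the
#' round trip preserves node names, the edge set, and all edge attributes
#' (`weight`, `rho`, `p`, `n_obs`).
#'
#' @param net an `igraph` network.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Read a network from GraphML
#'
#' @param path GraphML file.
#' @return an `igraph` network.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
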