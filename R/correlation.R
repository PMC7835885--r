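# Spearman correlation with Student-t significance, network construction
# at a p-value threshold, and the threshold sensitivity scan.

#' Pairwise Spearman correlation matrix with significance
#'
#' Computes, for every pair of variables, the Spearman rank correlation on
#' pairwise-complete observations (midranks for ties), its square, the
#' two-sided p-value from the Student-t approximation with n - 2 degrees of
#' freedom, and the pairwise sample count. Pairwise-complete use matches a
#' screening stage that blanks individual outlying values rather than
#' dropping subjects. Pairs with fewer than 4 complete observations, or a
#' constant column on the complete subset, are untestable: rho is `NA` and
#' p is 1, so they can never form an edge.
#'
#' @param table a `cohort_table` (or plain numeric matrix).
#' @return an object of class `correlation_result` with symmetric matrices
#'   `rho`, `rho2`, `p`, `n_obs`.
#' @export
spearman_matrix <- function(table) {
  X <- if (inherits(table, "cohort_table")) table$values else as.matrix(table)
  p <- ncol(X)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  rho <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  nobs <- matrix(0L, p, p, dimnames = list(vars, vars))
  if (!anyNA(X)) {
    rk <- apply(X, 2, rank, ties.method = "average")
    sds <- apply(rk, 2, stats::sd)
    rho <- suppressWarnings(stats::cor(rk))
    rho[sds == 0, ] <- NA_real_
    rho[, sds == 0] <- NA_real_
    nobs[] <- nrow(X)
  } else {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        ok <- stats::complete.cases(X[, i], X[, j])
        n <- sum(ok)
        nobs[i, j] <- nobs[j, i] <- n
        if (n < 4) next
        xi <- rank(X[ok, i], ties.method = "average")
        yj <- rank(X[ok, j], ties.method = "average")
        if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
        rho[i, j] <- rho[j, i] <- stats::cor(xi, yj)
      }
    }
    diag(nobs) <- colSums(!is.na(X))
  }
  diag(rho) <- 1
  pmat <- matrix(1, p, p, dimnames = list(vars, vars))
  off <- upper.tri(rho)
  pmat[off] <- spearman_pvalue(rho[off], nobs[off])
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  diag(pmat) <- 0
  structure(list(rho = rho, rho2 = rho^2, p = pmat, n_obs = nobs,
                 variables = vars),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d variables, %d testable pairs\n",
              length(x$variables), sum(!is.na(x$rho[upper.tri(x$rho)]))))
  invisible(x)
}

#' Two-sided p-value for a Spearman correlation
#'
#' Uses the Student-t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' with n - 2 degrees of freedom. `|rho| = 1` returns p = 0 by convention;
#' `n < 4` or missing rho returns p = 1 (untestable).
#'
#' @param rho Spearman correlation(s) in `[-1, 1]`.
#' @param n pairwise sample count(s).
#' @return two-sided p-value(s), vectorized over inputs.
#' @export
spearman_pvalue <- function(rho, n) {
  p <- rep(1, length(rho))
  exact <- !is.na(rho) & abs(rho) >= 1 & n >= 4
  p[exact] <- 0
  ok <- !is.na(rho) & abs(rho) < 1 & n >= 4
  t <- rho[ok] * sqrt((n[ok] - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t), df = n[ok] - 2)
  p
}

#' Build a physiological network at a significance threshold
#'
#' Links every pair of variables with `p < alpha`; the edge weight is the
#' squared Spearman correlation (so all weights are positive), and the
#' signed rho, p-value and pairwise sample count are retained as edge
#' attributes. Variables that end up with no significant correlation are
#' kept as isolated nodes rather than dropped.
#'
#' @param corr a `correlation_result`.
#' @param alpha significance threshold in `(0, 1]`.
#' @param meta optional variable metadata data frame (columns `id`,
#'   `short_name`, `category`, `units`) attached as vertex attributes.
#' @return an undirected `igraph` network with edge attributes `weight`
#'   (rho squared), `rho`, `p`, `n_obs`, and graph attribute `alpha`.
#' @export
build_network <- function(corr, alpha, meta = NULL) {
  stopifnot(inherits(corr, "correlation_result"), alpha > 0, alpha <= 1)
  vars <- corr$variables
  idx <- which(upper.tri(corr$p) & corr$p < alpha & !is.na(corr$rho),
               arr.ind = TRUE)
  edges <- data.frame(from = vars[idx[, 1]], to = vars[idx[, 2]],
                      weight = corr$rho2[idx], rho = corr$rho[idx],
                      p = corr$p[idx], n_obs = corr$n_obs[idx])
  vdf <- data.frame(name = vars, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    m <- meta[match(vars, meta$short_name), , drop = FALSE]
    # "var_id", not "id": GraphML reserves an id attribute per vertex
    vdf$var_id <- m$id; vdf$category <- m$category; vdf$units <- m$units
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g
}

#' Scan network topology over a grid of significance thresholds
#'
#' Rebuilds the network at each threshold of a decreasing grid and records
#' the full topology panel (density, connectedness, efficiency, L, T, CC,
#' analytic small-world index, scale-free fit), modularity per clustering
#' method, total strength, and the node-strength vector. Metrics undefined
#' at some threshold (e.g. the scale-free fit of a near-empty graph) are
#' recorded as `NA` and the scan continues.
#'
#' @param corr a `correlation_result`.
#' @param grid decreasing vector of thresholds in `(0, 1]`; the default
#'   spans the window from 0.05 down to 1e-6.
#' @param cluster_methods character subset of `c("louvain", "infomap")`.
#' @param seed integer seed for the clustering sweeps.
#' @return an object of class `threshold_scan` with a `summary` data frame
#'   (one row per alpha) and a `strength` matrix (alpha x node).
#' @export
threshold_scan <- function(corr,
                           grid = c(0.05, 0.01, 5e-3, 1e-3, 5e-4, 1e-4,
                                    1e-5, 1e-6),
                           cluster_methods = c("louvain", "infomap"),
                           seed = 1L) {
  stopifnot(inherits(corr, "correlation_result"))
  if (is.unsorted(rev(grid))) stop_named("grid must be sorted decreasing")
  if (any(grid <= 0 | grid > 1)) stop_named("grid values must lie in (0, 1]")
  cluster_methods <- match.arg(cluster_methods, several.ok = TRUE)
  rows <- list()
  strengths <- matrix(NA_real_, length(grid), length(corr$variables),
                      dimnames = list(format(grid, digits = 3),
                                      corr$variables))
  for (k in seq_along(grid)) {
    a <- grid[k]
    net <- build_network(corr, a)
    s <- node_strength(net)
    strengths[k, names(s)] <- s
    tc <- tryCatch(clustering_metrics(net),
                   error = function(e) list(T = NA_real_, CC = NA_real_))
    sw <- tryCatch(small_world(net, B = 0L)$SWI, error = function(e) NA_real_)
    sf <- tryCatch(scale_free_fit(net)$R2, error = function(e) NA_real_)
    L <- tryCatch(char_path_length(net), error = function(e) NA_real_)
    row <- data.frame(
      alpha = a,
      edges = igraph::ecount(net),
      density = net_density(net),
      connectedness = net_connectedness(net),
      efficiency = net_efficiency(net),
      L = L, T = tc$T, CC = tc$CC, SWI = sw, scale_free_R2 = sf,
      total_strength = sum(s))
    for (m in cluster_methods) {
      q <- if (igraph::ecount(net) == 0) NA_real_ else {
        part <- if (m == "louvain")
          louvain_communities(net, seed = derive_seed(seed, paste0(m, k)))
        else
          infomap_communities(net, seed = derive_seed(seed, paste0(m, k)))
        part$modularity
      }
      row[[paste0("modularity_", m)]] <- q
    }
    rows[[k]] <- row
  }
  structure(list(summary = do.call(rbind, rows), strength = strengths,
                 grid = grid),
            class = "threshold_scan")
}

#' Select the working significance threshold from a scan
#'
#' Returns the smallest threshold in the grid whose network keeps
#' connectedness at or above `min_connectedness` (default 0.95): the
#' compromise between discarding redundant collinear links and keeping the
#' network connected. If no threshold satisfies the constraint, the largest
#' grid value is returned with a warning.
#'
#' @param scan a `threshold_scan`.
#' @param min_connectedness minimum acceptable connectedness in `[0, 1]`.
#' @return the selected alpha.
#' @export
select_threshold <- function(scan, min_connectedness = 0.95) {
  stopifnot(inherits(scan, "threshold_scan"), nrow(scan$summary) > 0)
  ok <- which(scan$summary$connectedness >= min_connectedness)
  if (!length(ok)) {
    warn_named("no threshold reaches connectedness %.2f; returning largest grid value",
               min_connectedness)
    return(scan$grid[1])
  }
  scan$grid[max(ok)]
}
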