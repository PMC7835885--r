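# Pipeline orchestration: configuration validation, the full
# simulate/ingest -> preprocess -> correlate -> scan -> build -> analyze
# run, and the shared Fruchterman-Reingold layout for side-by-side
# network renderings.

#' Validate a run configuration
#'
#' A configuration is a named list (or YAML file read with
#' [read_run_config()]) holding the input choice and all analysis
#' settings. Every stochastic stage must have a seed: a single master
#' `seed` is mandatory, and per-stage seeds are derived from it with
#' [derive_seed()].
#'
#' Recognized fields (with defaults): `seed` (required); `input` (path of
#' a cohort CSV) or `simulate` (list passed to [cohort_spec()]; default, a
#' [default_cohort_spec()]); `normalize` (`"median-range"` or `"none"`,
#' default median-range); `rout_q` (default 0.01) or `rout = FALSE`;
#' `derive` (character vector of derived-variable ids, default none);
#' `grid` (threshold scan grid); `alpha` (fixed threshold; default, chosen
#' from the scan); `min_connectedness` (default 0.95); `cluster_method`
#' (`"louvain"`, `"infomap"`, or `"both"`, default both); `smallworld_B`
#' (default 100); `flow` (compute flow betweenness fields, default TRUE);
#' `attack` (logical, default FALSE) and `attack_reps` (default 50);
#' `out_dir` (default `NULL`: nothing written).
#'
#' @param cfg named list.
#' @return the completed configuration (invisibly classed `run_config`).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed))
    stop_named("run configuration must set an explicit master seed")
  defaults <- list(normalize = "median-range", rout = TRUE, rout_q = 0.01,
                   derive = character(),
                   grid = c(0.05, 0.01, 5e-3, 1e-3, 5e-4, 1e-4, 1e-5, 1e-6),
                   alpha = NULL, min_connectedness = 0.95,
                   cluster_method = "both", smallworld_B = 100L,
                   flow = TRUE, attack = FALSE, attack_reps = 50L,
                   qap_R = 1000L, out_dir = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$normalize %in% c("median-range", "none"))
    stop_named("normalize must be 'median-range' or 'none'")
  if (!cfg$cluster_method %in% c("louvain", "infomap", "both"))
    stop_named("cluster_method must be louvain, infomap, or both")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full physiological-network pipeline
#'
#' Executes, in order: cohort simulation (or CSV ingest), the outlier and
#' normality screens, optional derived variables, median/range
#' normalization, the Spearman correlation matrix, the threshold scan and
#' threshold selection, network construction, the topology summary panel,
#' centralities, community detection (with subclusters and the contracted
#' cluster graph), and optionally the attack curves. Every decision
#' (threshold chosen, outliers flagged) is logged in the returned report;
#' with `out_dir` set, tables, the GraphML network, and a JSON report are
#' written there alongside the verbatim configuration.
#'
#' @param cfg a `run_config` (or list validated by
#'   [validate_run_config()]).
#' @return a list report with elements `config`, `cohort`, `screen`,
#'   `shapiro`, `correlation`, `scan`, `alpha`, `network`, `topology`,
#'   `centrality`, `clusters`, and (optionally) `attacks`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  # --- input ---------------------------------------------------------
  planted <- NULL
  if (!is.null(cfg$input)) {
    tab <- read_cohort_csv(cfg$input)
    note("ingested cohort from %s", cfg$input)
  } else {
    spec <- if (is.null(cfg$simulate))
      default_cohort_spec(seed = derive_seed(cfg$seed, "simulate"))
    else do.call(cohort_spec,
                 c(cfg$simulate, list(seed = derive_seed(cfg$seed, "simulate"))))
    sim <- generate_cohort(spec)
    tab <- sim$table
    planted <- sim$partition
    note("simulated cohort: %d subjects x %d variables",
         nrow(tab$values), ncol(tab$values))
  }

  # --- preprocess ----------------------------------------------------
  screen <- NULL
  if (isTRUE(cfg$rout)) {
    rs <- rout_screen(tab, Q = cfg$rout_q)
    tab <- rs$table
    screen <- rs$report
    note("ROUT screen at Q = %g flagged %d cell(s)", cfg$rout_q,
         nrow(rs$report))
  }
  sw <- shapiro_screen(tab)
  note("Shapiro-Wilk screen: %d of %d variables non-normal at p < 0.05",
       sum(sw$p < 0.05, na.rm = TRUE), nrow(sw))
  if (length(cfg$derive)) {
    tab <- derive_variables(tab, cfg$derive)$table
    note("derived variables appended: %s", paste(cfg$derive, collapse = ", "))
  }
  if (cfg$normalize == "median-range") {
    tab <- normalize_median_range(tab)$table
    note("median/range normalization applied")
  }

  # --- correlation and threshold ------------------------------------
  corr <- spearman_matrix(tab)
  scan <- threshold_scan(corr, grid = cfg$grid,
                         cluster_methods = if (cfg$cluster_method == "both")
                           c("louvain", "infomap") else cfg$cluster_method,
                         seed = derive_seed(cfg$seed, "scan"))
  alpha <- if (!is.null(cfg$alpha)) cfg$alpha
           else select_threshold(scan, cfg$min_connectedness)
  note("significance threshold alpha = %g (min connectedness %.2f)",
       alpha, cfg$min_connectedness)
  net <- build_network(corr, alpha, meta = tab$meta)
  note("network: %d nodes, %d edges", igraph::vcount(net),
       igraph::ecount(net))

  # --- topology, centrality, communities ----------------------------
  topo <- topology_summary(net, B = cfg$smallworld_B,
                           seed = derive_seed(cfg$seed, "smallworld"),
                           flow = isTRUE(cfg$flow))
  centr <- data.frame(
    node = igraph::V(net)$name,
    degree = igraph::degree(net),
    strength = node_strength(net),
    eigencentrality = eigencentrality(net),
    row.names = NULL)
  if (isTRUE(cfg$flow)) centr$flow_betweenness <- flow_betweenness(net)

  parts <- list()
  if (cfg$cluster_method %in% c("louvain", "both"))
    parts$louvain <- louvain_communities(net,
                                         seed = derive_seed(cfg$seed, "louvain"))
  if (cfg$cluster_method %in% c("infomap", "both"))
    parts$infomap <- infomap_communities(net,
                                         seed = derive_seed(cfg$seed, "infomap"))
  main_part <- parts[[1]]
  note("clustering (%s): %d communities, Q = %.3f", main_part$method,
       max(main_part$membership), main_part$modularity)
  subparts <- subcluster(net, main_part, method = main_part$method,
                         seed = derive_seed(cfg$seed, "subcluster"))
  cluster_graph <- contract_clusters(net, main_part)
  recovery <- if (!is.null(planted))
    adjusted_rand_index(main_part, planted) else NA_real_
  if (!is.na(recovery))
    note("planted-block recovery: adjusted Rand = %.3f", recovery)

  attacks <- NULL
  if (isTRUE(cfg$attack)) {
    attacks <- lapply(c("random", "degree", "betweenness", "cascading"),
                      function(s) attack(net, s, reps = cfg$attack_reps,
                                         seed = derive_seed(cfg$seed, "attack")))
    names(attacks) <- c("random", "degree", "betweenness", "cascading")
    note("attack curves computed (random reps = %d)", cfg$attack_reps)
  }

  report <- list(config = unclass(cfg), cohort = tab, planted = planted,
                 screen = screen, shapiro = sw, correlation = corr,
                 scan = scan, alpha = alpha, network = net,
                 topology = topo, centrality = centr,
                 clusters = list(partitions = parts, subclusters = subparts,
                                 cluster_graph = cluster_graph,
                                 planted_recovery = recovery),
                 attacks = attacks, log = log)

  if (!is.null(cfg$out_dir)) write_report_bundle(report, cfg$out_dir)
  report
}

# serialize the machine-readable pieces of a pipeline report
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  cfg <- report$config
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, pth("config.yaml"))
  write_cohort_csv(report$cohort, pth("cohort.csv"))
  utils::write.csv(report$correlation$rho, pth("rho.csv"))
  utils::write.csv(report$correlation$p, pth("p.csv"))
  utils::write.csv(report$scan$summary, pth("threshold_scan.csv"),
                   row.names = FALSE)
  write_edge_list(report$network, pth("edges.csv"))
  write_network_graphml(report$network, pth("network.graphml"))
  utils::write.csv(report$centrality, pth("centrality.csv"),
                   row.names = FALSE)
  main <- report$clusters$partitions[[1]]
  sub <- report$clusters$subclusters
  memb <- data.frame(node = names(main$membership),
                     community = unname(main$membership))
  memb$subcommunity <- vapply(seq_len(nrow(memb)), function(i) {
    sp <- sub[[as.character(memb$community[i])]]
    unname(sp$membership[memb$node[i]])
  }, numeric(1))
  utils::write.csv(memb, pth("membership.csv"), row.names = FALSE)
  write_network_graphml(report$clusters$cluster_graph,
                        pth("cluster_graph.graphml"))
  json <- list(alpha = report$alpha,
               topology = as.list(report$topology),
               modularity = lapply(report$clusters$partitions,
                                   function(p) p$modularity),
               planted_recovery = report$clusters$planted_recovery,
               log = report$log)
  jsonlite::write_json(json, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(report$attacks)) {
    curves <- do.call(rbind, lapply(report$attacks, function(a)
      data.frame(strategy = a$strategy,
                 step = seq_along(a$connectivity_loss),
                 removed_fraction = a$removed_fraction,
                 loss = a$connectivity_loss)))
    utils::write.csv(curves, pth("attack_curves.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Shared layout for two networks
#'
#' Merges the edge lists of both networks (union by node name) and runs a
#' seeded Fruchterman-Reingold force-directed layout on the merged graph,
#' so every shared node receives identical coordinates in both renderings
#' and the two networks can be contrasted side by side.
#'
#' @param net1,net2 undirected `igraph` networks with node names.
#' @param seed integer seed.
#' @return data frame with `node`, `x`, `y`; attribute `algorithm`.
#' @export
merged_layout <- function(net1, net2, seed = 1L) {
  merged <- igraph::union(net1, net2)
  set.seed(seed)
  xy <- igraph::layout_with_fr(merged)
  out <- data.frame(node = igraph::V(merged)$name, x = xy[, 1], y = xy[, 2])
  attr(out, "algorithm") <- "fruchterman-reingold"
  attr(out, "seed") <- seed
  out
}
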