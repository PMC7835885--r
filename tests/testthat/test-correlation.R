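test_that("Spearman matrix matches hand values and the rank-formula oracle", {
  # monotone pairs
  X <- cbind(x = 1:5, y = c(2, 4, 6, 8, 10))
  expect_equal(spearman_matrix(X)$rho["x", "y"], 1)
  X2 <- cbind(x = 1:3, y = 3:1)
  expect_equal(spearman_matrix(X2)$rho["x", "y"], -1)
  # no-ties rank-difference formula: 1 - 6*2/(4*15) = 0.8
  X3 <- cbind(x = 1:4, y = c(1, 3, 2, 4))
  expect_equal(spearman_matrix(X3)$rho["x", "y"], 0.8)

  # brute-force oracle equivalence on random 10 x 6 tables, with ties
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(sample(1:8, 60, replace = TRUE) + rnorm(60, 0, 0.01), 10, 6)
    X[sample(60, 3)] <- X[1]  # force ties
    res <- spearman_matrix(X)
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(res$rho[i, j], oracle_spearman(X[, i], X[, j]),
                   tolerance = 1e-12)
  }
})

test_that("pairwise-complete correlation uses midranks over shared observations", {
  X <- cbind(x = c(1, 2, 3, 4, 5, NA), y = c(2, 1, 4, 3, NA, 6))
  res <- spearman_matrix(X)
  ok <- 1:4
  expect_equal(res$rho["x", "y"], oracle_spearman(X[ok, 1], X[ok, 2]))
  expect_equal(res$n_obs["x", "y"], 4)
  # pairs with < 4 complete observations are untestable
  X2 <- cbind(x = c(1, 2, 3, NA, NA, NA), y = c(NA, NA, NA, 1, 2, 3),
              z = 1:6)
  res2 <- spearman_matrix(X2)
  expect_true(is.na(res2$rho["x", "y"]))
  expect_identical(res2$p["x", "y"], 1)
})

test_that("constant columns give missing correlations, never NaN edges", {
  X <- cbind(x = rep(2, 10), y = rnorm(10), z = rnorm(10))
  res <- spearman_matrix(X)
  expect_true(is.na(res$rho["x", "y"]))
  net <- build_network(res, alpha = 1)
  el <- igraph::as_edgelist(net)
  expect_false("x" %in% el)
})

test_that("Spearman p-values follow the Student-t approximation", {
  expect_equal(spearman_pvalue(0, 100), 1)
  expect_equal(spearman_pvalue(1, 10), 0)
  expect_equal(spearman_pvalue(-1, 10), 0)
  # rho = 0.8, n = 4: t = 0.8 sqrt(2 / 0.36), df = 2
  t <- 0.8 * sqrt(2 / 0.36)
  expect_equal(spearman_pvalue(0.8, 4), 2 * pt(-t, df = 2),
               tolerance = 1e-12)
  expect_lt(abs(spearman_pvalue(0.8, 4) - 0.2), 0.005)
  expect_equal(spearman_pvalue(0.5, 3), 1)  # untestable
})

test_that("network construction thresholds p, keeps isolates, weights by rho^2", {
  rho <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.2, 0.1, 0.2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(c(0, 5e-4, 0.5, 5e-4, 0, 0.05, 0.5, 0.05, 0), 3, 3,
              dimnames = dimnames(rho))
  corr <- corr_from_matrices(rho, p)
  net <- build_network(corr, alpha = 0.001)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::vcount(net), 3)   # c kept as isolate
  expect_equal(igraph::E(net)$weight, 0.81)
  expect_equal(igraph::E(net)$rho, 0.9)
  full <- build_network(corr, alpha = 1)
  expect_equal(igraph::ecount(full), 3)  # complete graph at alpha = 1
  empty <- build_network(corr, alpha = 1e-9)
  expect_equal(igraph::ecount(empty), 0)
})

test_that("threshold scan is monotone and removes the weakest links first", {
  sim <- generate_cohort(default_cohort_spec(seed = 2, n_subjects = 120))
  corr <- spearman_matrix(sim$table)
  scan <- threshold_scan(corr, cluster_methods = "louvain", seed = 1)
  expect_true(all(diff(scan$summary$edges) <= 0))
  # weakest-link property across consecutive thresholds
  grid <- scan$grid
  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  }
  for (k in seq_len(length(grid) - 1)) {
    big <- build_network(corr, grid[k])
    small <- build_network(corr, grid[k + 1])
    kb <- edge_keys(big); ks <- edge_keys(small)
    if (!length(ks) || length(ks) == length(kb)) next
    wb <- igraph::E(big)$weight
    expect_lte(mean(wb[!kb %in% ks]), mean(wb[kb %in% ks]))
  }
  # single-alpha grid at 1 is the fully connected entry
  one <- threshold_scan(corr, grid = 1, cluster_methods = "louvain")
  expect_equal(one$summary$density, 1)
})

test_that("modularity rises as the threshold tightens on planted structure", {
  sim <- generate_cohort(default_cohort_spec(seed = 31))
  corr <- spearman_matrix(sim$table)
  scan <- threshold_scan(corr, grid = c(0.05, 0.001),
                         cluster_methods = "louvain", seed = 9)
  q <- scan$summary$modularity_louvain
  expect_gte(q[2], q[1])
})

test_that("threshold selection applies the connectedness rule", {
  mk_scan <- function(conn, grid) {
    structure(list(summary = data.frame(alpha = grid, connectedness = conn),
                   grid = grid),
              class = "threshold_scan")
  }
  grid <- c(0.05, 0.01, 0.001, 0.0001)
  expect_equal(select_threshold(mk_scan(c(1, 0.98, 0.96, 0.7), grid)), 0.001)
  expect_equal(select_threshold(mk_scan(c(1, 0.98, 0.96, 0.7), grid),
                                min_connectedness = 0), 0.0001)
  expect_warning(a <- select_threshold(mk_scan(c(0.5, 0.4, 0.3, 0.2), grid)),
                 "no threshold")
  expect_equal(a, 0.05)
})

test_that("null cohorts produce edges at the nominal type-I rate", {
  # independent variables: fraction of p < 0.01 edges matches 0.01
  frac <- vapply(1:60, function(s) {
    set.seed(s)
    X <- matrix(rnorm(150 * 10), 150, 10)
    p <- spearman_matrix(X)$p
    mean(p[upper.tri(p)] < 0.01)
  }, numeric(1))
  n_tests <- 60 * 45
  se <- sqrt(0.01 * 0.99 / n_tests)
  expect_lt(abs(mean(frac) - 0.01), 3 * se)
})
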