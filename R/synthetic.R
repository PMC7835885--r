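#' Specify one planted correlation block
#'
#' A block is a set of variables that share a common latent Gaussian
#' correlation, emulating one functional cluster of biomarkers (e.g. body
#' size, lipids, red-cell indices) in which variables co-vary through shared
#' physiology.
#'
#' @param label character block label.
#' @param size number of variables in the block (>= 1).
#' @param within_rho latent Gaussian correlation inside the block, in `[0, 1)`.
#' @return an object of class `block_spec`.
#' @export
block_spec <- function(label, size, within_rho) {
  stopifnot(is.character(label), length(label) == 1L)
  if (size < 1) stop_named("block '%s': size must be >= 1", label)
  if (within_rho < 0 || within_rho >= 1)
    stop_named("block '%s': within_rho must lie in [0, 1)", label)
  structure(list(label = label, size = as.integer(size),
                 within_rho = within_rho), class = "block_spec")
}

#' Specify a synthetic cohort
#'
#' Defines a cohort drawn from a Gaussian copula with block-constant latent
#' correlation: `within_rho` inside each block, `between_rho` across blocks.
#' Marginals are transformed by the probability-integral transform to
#' asymmetric, leptokurtic families (lognormal by default), matching the
#' shape of clinical biomarker distributions. Optional gross outliers and
#' missing-completely-at-random cells exercise the screening and
#' pairwise-complete correlation stages.
#'
#' @param n_subjects number of subjects (rows).
#' @param blocks list of [block_spec()] objects.
#' @param between_rho latent correlation across blocks; must be smaller in
#'   magnitude than every within-block correlation.
#' @param marginal_family one of `"lognormal"`, `"gamma"`, `"normal"`.
#' @param marginal_params optional data frame with columns `par1`, `par2`
#'   (one row per variable): meanlog/sdlog, shape/scale, or mean/sd.
#' @param outlier_rate per-cell probability of a gross outlier, in `[0, 1]`.
#' @param outlier_magnitude outlier displacement in multiples of the column
#'   IQR.
#' @param missing_rate per-cell probability of a missing value, in `[0, 1]`.
#' @param seed integer seed; required for reproducibility.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, blocks, between_rho = 0.1,
                        marginal_family = c("lognormal", "gamma", "normal"),
                        marginal_params = NULL,
                        outlier_rate = 0, outlier_magnitude = 5,
                        missing_rate = 0, seed) {
  marginal_family <- match.arg(marginal_family)
  stopifnot(n_subjects >= 1, length(blocks) >= 1)
  if (missing(seed)) stop_named("cohort_spec requires an explicit seed")
  if (!all(vapply(blocks, inherits, logical(1), "block_spec")))
    stop_named("blocks must be a list of block_spec objects")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop_named("outlier_rate must lie in [0, 1]")
  wr <- vapply(blocks, `[[`, numeric(1), "within_rho")
  if (between_rho < 0 || between_rho >= 1 ||
      (length(wr) > 1 && abs(between_rho) >= min(wr)))
    stop_named("|between_rho| must be < min within_rho and lie in [0, 1)")
  if (outlier_rate > 0 && n_subjects < 10)
    warn_named("outlier injection with n_subjects < 10 is unreliable")
  p <- sum(vapply(blocks, `[[`, integer(1), "size"))
  if (is.null(marginal_params)) {
    marginal_params <- switch(marginal_family,
      lognormal = data.frame(par1 = rep(0, p),   par2 = rep(0.5, p)),
      gamma     = data.frame(par1 = rep(2, p),   par2 = rep(1, p)),
      normal    = data.frame(par1 = rep(0, p),   par2 = rep(1, p)))
  }
  if (nrow(marginal_params) != p)
    stop_named("marginal_params must have one row per variable (%d)", p)
  structure(list(n_subjects = as.integer(n_subjects), blocks = blocks,
                 between_rho = between_rho, marginal_family = marginal_family,
                 marginal_params = marginal_params,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default six-block cohort specification
#'
#' Six functional blocks of 8-12 variables (59 total), 150 subjects, latent
#' within-block correlation 0.6 and between-block correlation 0.1, lognormal
#' marginals. These are the standing study conditions used throughout the
#' package's examples and checks.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size, default 150.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(seed, n_subjects = 150) {
  sizes <- c(12L, 11L, 10L, 9L, 9L, 8L)
  labels <- c("size", "endocrine", "lipids", "immune", "redcell", "gas")
  blocks <- Map(block_spec, labels, sizes, rep(0.6, 6))
  cohort_spec(n_subjects = n_subjects, blocks = unname(blocks),
              between_rho = 0.1, marginal_family = "lognormal", seed = seed)
}

# Block-constant latent correlation matrix implied by a cohort_spec.
latent_correlation <- function(spec) {
  sizes <- vapply(spec$blocks, `[[`, integer(1), "size")
  p <- sum(sizes)
  block_of <- rep(seq_along(sizes), sizes)
  R <- matrix(spec$between_rho, p, p)
  for (b in seq_along(sizes)) {
    idx <- which(block_of == b)
    R[idx, idx] <- spec$blocks[[b]]$within_rho
  }
  diag(R) <- 1
  R
}

# Table-1-style measurement categories, cycled over blocks.
.categories <- c("Vital signs", "Anthropometric measures", "Bioimpedance",
                 "Hematic biometry", "Blood chemistry", "Molecular biology",
                 "Spirometry")

#' Construct a cohort table
#'
#' @param values numeric subjects-by-variables matrix (missing entries
#'   permitted).
#' @param meta data frame with columns `id`, `short_name`, `category`,
#'   `units`, one row per column of `values`.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(values, meta) {
  stopifnot(is.matrix(values), is.data.frame(meta))
  if (ncol(values) != nrow(meta))
    stop_named("metadata rows (%d) must match value columns (%d)",
               nrow(meta), ncol(values))
  need <- c("id", "short_name", "category", "units")
  if (!all(need %in% names(meta)))
    stop_named("metadata must have columns id, short_name, category, units")
  if (anyDuplicated(meta$id)) stop_named("variable ids must be unique")
  colnames(values) <- meta$short_name
  structure(list(values = values, meta = meta), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Generate a synthetic cohort with planted correlation blocks
#'
#' Draws a latent multivariate normal sample with the block-constant
#' correlation of the spec (Gaussian copula), maps each column to its
#' marginal family by the probability-integral transform, then optionally
#' injects gross outliers and missing-completely-at-random cells. The
#' planted block membership is returned as the ground-truth partition for
#' community-recovery checks. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `table` (a `cohort_table`) and `partition`
#'   (a `partition` holding the planted block membership).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- latent_correlation(spec)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_named("latent correlation matrix is not positive definite (min eigenvalue %.3e)",
               min(ev))
  p <- ncol(R)
  n <- spec$n_subjects
  sizes <- vapply(spec$blocks, `[[`, integer(1), "size")
  labels <- vapply(spec$blocks, `[[`, character(1), "label")
  block_of <- rep(seq_along(sizes), sizes)

  set.seed(derive_seed(spec$seed, "copula"))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
  U <- stats::pnorm(Z)
  pp <- spec$marginal_params
  X <- switch(spec$marginal_family,
    lognormal = vapply(seq_len(p), function(j)
      stats::qlnorm(U[, j], meanlog = pp$par1[j], sdlog = pp$par2[j]),
      numeric(n)),
    gamma = vapply(seq_len(p), function(j)
      stats::qgamma(U[, j], shape = pp$par1[j], scale = pp$par2[j]),
      numeric(n)),
    normal = vapply(seq_len(p), function(j)
      stats::qnorm(U[, j], mean = pp$par1[j], sd = pp$par2[j]),
      numeric(n)))
  X <- matrix(X, n, p)
  rownames(X) <- sprintf("S%03d", seq_len(n))

  within_idx <- unlist(lapply(sizes, seq_len))
  meta <- data.frame(
    id = seq_len(p),
    short_name = sprintf("%s_%02d", labels[block_of], within_idx),
    category = .categories[((block_of - 1L) %% length(.categories)) + 1L],
    units = "a.u.",
    stringsAsFactors = FALSE)
  tab <- cohort_table(X, meta)

  if (spec$missing_rate > 0) {
    set.seed(derive_seed(spec$seed, "missing"))
    mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
    tab$values[mask] <- NA_real_
  }
  if (spec$outlier_rate > 0) {
    out <- inject_outliers(tab, rate = spec$outlier_rate,
                           magnitude = spec$outlier_magnitude,
                           seed = derive_seed(spec$seed, "outliers"))
    tab <- out$table
  }
  membership <- stats::setNames(block_of, meta$short_name)
  part <- new_partition(membership, method = "planted", seed = spec$seed)
  list(table = tab, partition = part)
}

#' Inject gross outliers into a cohort table
#'
#' Displaces a Bernoulli(`rate`) subset of cells by `magnitude` times the
#' column IQR, with random sign, mimicking measurement or transcription
#' error rather than biological tails. Columns with zero IQR are skipped and
#' reported. Displaced positions are logged.
#'
#' @param table a `cohort_table`.
#' @param rate per-cell displacement probability in `[0, 1]`.
#' @param magnitude displacement in multiples of the column IQR.
#' @param seed integer seed.
#' @return list with `table` (displaced copy), `positions` (data frame of
#'   subject row, variable, original and displaced value), and
#'   `skipped_variables`.
#' @export
inject_outliers <- function(table, rate, magnitude, seed) {
  stopifnot(inherits(table, "cohort_table"), rate >= 0, rate <= 1,
            magnitude > 0)
  X <- table$values
  if (rate == 0)
    return(list(table = table,
                positions = data.frame(subject = integer(), variable = character(),
                                       original = numeric(), displaced = numeric()),
                skipped_variables = character()))
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  hit <- matrix(stats::runif(n * p) < rate, n, p) & !is.na(X)
  sgn <- matrix(sign(stats::runif(n * p) - 0.5), n, p)
  iqr <- apply(X, 2, stats::IQR, na.rm = TRUE)
  skipped <- colnames(X)[iqr == 0 & colSums(hit) > 0]
  pos <- NULL
  for (j in seq_len(p)) {
    if (iqr[j] == 0) next
    rows <- which(hit[, j])
    if (!length(rows)) next
    orig <- X[rows, j]
    X[rows, j] <- orig + sgn[rows, j] * magnitude * iqr[j]
    pos <- rbind(pos, data.frame(subject = rows,
                                 variable = colnames(X)[j],
                                 original = orig, displaced = X[rows, j]))
  }
  if (is.null(pos))
    pos <- data.frame(subject = integer(), variable = character(),
                      original = numeric(), displaced = numeric())
  rownames(pos) <- NULL
  out <- table
  out$values <- X
  list(table = out, positions = pos, skipped_variables = skipped)
}
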