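# Data-processing stage: median/range normalization, robust outlier
# screening with FDR control, normality screening, and clinically standard
# derived variables.

#' Median/range normalization
#'
#' Biomarker panels mix units and scales, and their distributions are
#' typically asymmetric and leptokurtic, so the median is used as the
#' center and the range as the dispersion: `x = (V - Me) / (Max - Min)`
#' per variable. Rank-based correlation downstream is unaffected by this
#' affine map; normalization matters for display and for
#' community-structure contrast. Missing entries propagate.
#'
#' @param table a `cohort_table`.
#' @return list with `table` (normalized copy) and `params` (data frame
#'   with `variable`, `Me`, `Max`, `Min`) to allow inversion.
#' @export
normalize_median_range <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  X <- table$values
  me <- apply(X, 2, stats::median, na.rm = TRUE)
  mx <- apply(X, 2, max, na.rm = TRUE)
  mn <- apply(X, 2, min, na.rm = TRUE)
  const <- which(mx - mn <= 0 | !is.finite(mx - mn))
  if (length(const))
    stop_named("constant variable(s): %s (normalization undefined)",
               paste(colnames(X)[const], collapse = ", "))
  out <- table
  out$values <- sweep(sweep(X, 2, me, "-"), 2, mx - mn, "/")
  list(table = out,
       params = data.frame(variable = colnames(X), Me = me, Max = mx,
                           Min = mn, row.names = NULL))
}

#' Invert a median/range normalization
#'
#' @param table normalized `cohort_table`.
#' @param params the `params` data frame from [normalize_median_range()].
#' @return a `cohort_table` on the original scale.
#' @export
denormalize <- function(table, params) {
  stopifnot(inherits(table, "cohort_table"))
  stopifnot(identical(colnames(table$values), params$variable))
  out <- table
  out$values <- sweep(sweep(table$values, 2, params$Max - params$Min, "*"),
                      2, params$Me, "+")
  out
}

#' Robust outlier screen with FDR control (ROUT-style)
#'
#' Screens each variable independently with a robust constant fit: the
#' median is the fitted location; the robust scale (RSDR) is the 68.27th
#' percentile of absolute residuals with the small-sample correction
#' `n / (n - 1)`. Residuals are converted to two-sided t-tail p-values
#' (df = n - 1) and outliers are flagged by Benjamini-Hochberg FDR control
#' at level `Q`. Flagged values become missing cells - single values are
#' discarded, not whole subjects. The screen is iterated until no new cell
#' is flagged, so it is idempotent on its own output.
#'
#' @param table a `cohort_table`.
#' @param Q desired maximum false-discovery rate of outlier calls, in
#'   `(0, 1]`; default 0.01.
#' @return list with `table` (flagged cells set to `NA`) and `report`
#'   (data frame with `subject`, `variable`, `value`, `p_adj`), plus
#'   `skipped_variables` (zero robust scale or fewer than 10 values).
#' @export
rout_screen <- function(table, Q = 0.01) {
  stopifnot(inherits(table, "cohort_table"), Q > 0, Q <= 1)
  X <- table$values
  report <- NULL
  skipped <- character()
  for (j in seq_len(ncol(X))) {
    repeat {
      ok <- which(!is.na(X[, j]))
      if (length(ok) < 10) {
        skipped <- union(skipped, colnames(X)[j]); break
      }
      x <- X[ok, j]
      r <- x - stats::median(x)
      n <- length(x)
      rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - 1)
      if (rsdr <= 0) { skipped <- union(skipped, colnames(X)[j]); break }
      p <- 2 * stats::pt(-abs(r) / rsdr, df = n - 1)
      flag <- stats::p.adjust(p, method = "BH") < Q
      if (!any(flag)) break
      hit <- ok[flag]
      report <- rbind(report,
                      data.frame(subject = hit, variable = colnames(X)[j],
                                 value = X[hit, j],
                                 p_adj = stats::p.adjust(p, "BH")[flag]))
      X[hit, j] <- NA_real_
    }
  }
  if (is.null(report))
    report <- data.frame(subject = integer(), variable = character(),
                         value = numeric(), p_adj = numeric())
  rownames(report) <- NULL
  out <- table
  out$values <- X
  list(table = out, report = report, skipped_variables = skipped)
}

#' Shapiro-Wilk normality screen
#'
#' Reports the Shapiro-Wilk statistic and p-value per variable. The screen
#' justifies the use of rank-based correlation downstream; it never
#' modifies the data. Variables with fewer than 3 (or more than 5000)
#' non-missing values are marked untestable.
#'
#' @param table a `cohort_table`.
#' @return data frame with `variable`, `n`, `W`, `p`, `testable`.
#' @export
shapiro_screen <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  res <- lapply(seq_len(ncol(table$values)), function(j) {
    x <- table$values[, j]
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(x) > 5000 || length(unique(x)) < 2)
      return(data.frame(variable = colnames(table$values)[j], n = length(x),
                        W = NA_real_, p = NA_real_, testable = FALSE))
    sw <- stats::shapiro.test(x)
    data.frame(variable = colnames(table$values)[j], n = length(x),
               W = unname(sw$statistic), p = sw$p.value, testable = TRUE)
  })
  do.call(rbind, res)
}

# Formulas for clinically standard derived variables. Parents are referred
# to by the Table-1-style short names; Ht is in cm, Gluc in mg/dL
# (converted to mmol/L for the HOMA indices), Ins in mIU/L.
.derived_formulas <- list(
  MAP      = list(parents = c("SBP", "DBP"),
                  fn = function(d) (d$SBP + 2 * d$DBP) / 3),
  BMI      = list(parents = c("Wt", "Ht"),
                  fn = function(d) d$Wt / (d$Ht / 100)^2),
  BFp      = list(parents = c("BF", "Wt"), fn = function(d) 100 * d$BF / d$Wt),
  FFMp     = list(parents = c("BF", "Wt"),
                  fn = function(d) 100 * (d$Wt - d$BF) / d$Wt),
  SMMp     = list(parents = c("SMM", "Wt"), fn = function(d) 100 * d$SMM / d$Wt),
  TBWp     = list(parents = c("TBW", "Wt"), fn = function(d) 100 * d$TBW / d$Wt),
  ECWp     = list(parents = c("ECW", "TBW"), fn = function(d) 100 * d$ECW / d$TBW),
  ICWp     = list(parents = c("ICW", "TBW"), fn = function(d) 100 * d$ICW / d$TBW),
  Neup     = list(parents = c("Neut", "Leuk"), fn = function(d) 100 * d$Neut / d$Leuk),
  Lymp     = list(parents = c("Lymph", "Leuk"), fn = function(d) 100 * d$Lymph / d$Leuk),
  Monop    = list(parents = c("Mono", "Leuk"), fn = function(d) 100 * d$Mono / d$Leuk),
  Eosp     = list(parents = c("Eos", "Leuk"), fn = function(d) 100 * d$Eos / d$Leuk),
  Basop    = list(parents = c("Baso", "Leuk"), fn = function(d) 100 * d$Baso / d$Leuk),
  Cast1    = list(parents = c("Chol", "HDL"), fn = function(d) d$Chol / d$HDL),
  Cast2    = list(parents = c("LDL", "HDL"), fn = function(d) d$LDL / d$HDL),
  HOMA_IR  = list(parents = c("Gluc", "Ins"),
                  fn = function(d) (d$Gluc / 18.016) * d$Ins / 22.5),
  HOMA_beta = list(parents = c("Gluc", "Ins"),
                  fn = function(d) 20 * d$Ins / (d$Gluc / 18.016 - 3.5)),
  BUN      = list(parents = "Urea", fn = function(d) d$Urea / 2.14),
  rel      = list(parents = c("FEV1", "FVC"), fn = function(d) d$FEV1 / d$FVC)
)

#' Names of supported derived variables
#' @return character vector of derived-variable identifiers.
#' @export
derived_variable_names <- function() names(.derived_formulas)

#' Append clinically standard derived variables
#'
#' Computes the requested derived columns (mean arterial pressure, body
#' mass index, bioimpedance proportions, differential leukocyte
#' proportions, Castelli risk indices, HOMA-IR and HOMA-beta, blood urea
#' nitrogen, FEV1/FVC ratio) from their parent variables and appends them
#' to the table. Parent columns are never mutated. A missing parent value
#' yields a missing derived cell; division by zero (or a non-finite result)
#' is reported and set missing.
#'
#' @param table a `cohort_table`.
#' @param requested character vector of derived ids (see
#'   [derived_variable_names()]).
#' @return list with `table` (columns appended) and `report` (data frame of
#'   derived cells set missing for non-finite results).
#' @export
derive_variables <- function(table, requested) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(requested, names(.derived_formulas))
  if (length(unknown))
    stop_named("unknown derived variable(s): %s", paste(unknown, collapse = ", "))
  X <- table$values
  meta <- table$meta
  report <- NULL
  for (id in requested) {
    f <- .derived_formulas[[id]]
    missing_parents <- setdiff(f$parents, colnames(X))
    if (length(missing_parents))
      stop_named("derived variable %s: missing parent(s) %s", id,
                 paste(missing_parents, collapse = ", "))
    d <- as.data.frame(X[, f$parents, drop = FALSE])
    names(d) <- f$parents
    v <- f$fn(d)
    bad <- which(!is.finite(v) & rowSums(is.na(d)) == 0)
    if (length(bad)) {
      report <- rbind(report, data.frame(subject = bad, variable = id))
      v[bad] <- NA_real_
    }
    v[!is.finite(v)] <- NA_real_
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- id
    meta <- rbind(meta, data.frame(id = max(meta$id) + 1L, short_name = id,
                                   category = "Derived", units = "derived"))
  }
  if (is.null(report))
    report <- data.frame(subject = integer(), variable = character())
  list(table = cohort_table(X, meta), report = report)
}
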