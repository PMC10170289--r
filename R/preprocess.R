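# Preprocessing for compositional abundance tables and metabolite matrices.
# Conventions: standard deviations use the n-1 (sample) convention throughout,
# consistent with the F-distribution control limits downstream.

#' Close each sample to relative abundances
#'
#' Divides every sample (row) by its total so rows sum to one. Idempotent and
#' invariant to per-sample scaling, which is why it stands in for rarefaction:
#' every downstream statistic here depends on the composition only.
#'
#' @param data Abundance tibble (`sample_id` + numeric feature columns), no
#'   missing values (impute first with [min_impute()]).
#' @return Tibble of the same shape with rows summing to 1.
#' @examples
#' tb <- tibble::tibble(sample_id = "s1", a = 2, b = 2, c = 4)
#' to_relative_abundance(tb)
#' @export
to_relative_abundance <- function(data) {
  m <- abund_matrix(data)
  if (anyNA(m)) abort("table contains missing values; run min_impute() first")
  check_nonnegative(m)
  tot <- rowSums(m)
  zero <- rownames(m)[tot == 0]
  if (length(zero) > 0) {
    abort(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  }
  as_abund_tbl(m / tot, state = "relative")
}

#' Impute missing values with each feature's observed minimum
#'
#' Features missing in more than `max_missing_fraction` of samples are dropped
#' (the count is reported); remaining missing cells are replaced by the
#' feature's minimum observed value. Observed values are never changed.
#'
#' @param data Abundance tibble, possibly with `NA` cells.
#' @param max_missing_fraction Drop features whose missing fraction exceeds
#'   this bound (default 0.25, i.e. keep features missed in at most 25% of
#'   samples).
#' @return Tibble with no missing cells.
#' @export
min_impute <- function(data, max_missing_fraction = 0.25) {
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1) {
    abort("`max_missing_fraction` must be in [0, 1]")
  }
  m <- abund_matrix(data)
  frac <- colMeans(is.na(m))
  drop <- frac > max_missing_fraction
  if (any(drop)) {
    message(sprintf("min_impute: dropped %d feature(s) missing in > %.0f%% of samples",
                    sum(drop), 100 * max_missing_fraction))
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) == 0) abort("all features dropped by missingness filter")
  all_na <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(all_na) > 0) {
    abort(sprintf("feature(s) with no observed values, no minimum exists: %s",
                  paste(all_na, collapse = ", ")))
  }
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- min(m[!nas, j])
  }
  as_abund_tbl(m, state = abund_state(data))
}

#' Filter features by prevalence
#'
#' Retains features with nonzero abundance in at least `min_prevalence` of
#' samples, preserving feature order. Used to stabilise the reference PCA
#' model against features observed in almost no reference sample.
#'
#' @param data Relative-abundance tibble.
#' @param min_prevalence Required fraction of samples with nonzero abundance.
#' @return Tibble restricted to the retained features.
#' @export
prevalence_filter <- function(data, min_prevalence = 0.1) {
  if (!is.numeric(min_prevalence) || min_prevalence < 0 || min_prevalence > 1) {
    abort("`min_prevalence` must be in [0, 1]")
  }
  m <- abund_matrix(data)
  keep <- colMeans(m > 0) >= min_prevalence
  if (!any(keep)) abort("prevalence filter removed every feature")
  as_abund_tbl(m[, keep, drop = FALSE], state = abund_state(data))
}

default_pseudocount <- function(m) {
  nz <- m[m > 0]
  if (length(nz) == 0) abort("cannot choose a pseudocount: all values are zero")
  min(nz) / 2
}

#' Log-ratio transform a relative-abundance table
#'
#' The centred log-ratio (`"clr"`) maps each sample to
#' `log(x + pseudocount) - mean(log(x + pseudocount))`; `"log-relative"` is the
#' plain elementwise `log(x + pseudocount)`. CLR is the default input space
#' for the normobiotic PCA model: it moves compositions into an approximately
#' Euclidean geometry where elliptical confidence regions make sense.
#'
#' @param data Relative-abundance tibble (rows sum to 1).
#' @param method `"clr"` or `"log-relative"`.
#' @param pseudocount Positive offset added before the log; default is half
#'   the smallest nonzero value in the table (multiplicative-replacement
#'   heuristic).
#' @return Transformed tibble; the pseudocount used is recorded in the
#'   `"pseudocount"` attribute so test samples can be transformed identically.
#' @export
transform_abundance <- function(data, method = c("clr", "log-relative"),
                                pseudocount = NULL) {
  method <- match.arg(method)
  m <- abund_matrix(data)
  if (anyNA(m)) abort("table contains missing values; run min_impute() first")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) {
    abort("rows must sum to 1; run to_relative_abundance() first")
  }
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(m)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number")
  }
  lg <- log(m + pseudocount)
  if (method == "clr") lg <- lg - rowMeans(lg)
  out <- as_abund_tbl(lg, state = "transformed")
  attr(out, "pseudocount") <- pseudocount
  attr(out, "transform") <- method
  out
}

#' Per-feature z-scores after log2 transformation
#'
#' Metabolite concentrations are compared between groups as z-scores centred
#' at 0 and standardised after log2 transformation: per feature, take log2,
#' subtract the feature mean, and divide by the feature standard deviation
#' (n-1 convention).
#'
#' @param data Tibble of strictly positive values (impute first).
#' @return Tibble whose feature columns have mean 0 and sd 1.
#' @export
log2_zscore <- function(data) {
  m <- abund_matrix(data)
  if (anyNA(m)) abort("table contains missing values; run min_impute() first")
  if (any(m <= 0)) abort("log2_zscore requires strictly positive values")
  lg <- log2(m)
  mu <- colMeans(lg)
  sd_ <- apply(lg, 2, stats::sd)
  zv <- colnames(m)[sd_ == 0]
  if (length(zv) > 0) {
    abort(sprintf("zero-variance feature(s): %s", paste(zv, collapse = ", ")))
  }
  as_abund_tbl(sweep(sweep(lg, 2, mu), 2, sd_, "/"), state = "transformed")
}

#' Pareto scaling
#'
#' Centres each feature and divides by the square root of its standard
#' deviation — the conventional metabolomics compromise between no scaling and
#' full autoscaling (applied after log transformation of concentrations).
#'
#' @param data Tibble of finite values.
#' @return Pareto-scaled tibble.
#' @export
pareto_scale <- function(data) {
  m <- abund_matrix(data)
  if (anyNA(m) || any(!is.finite(m))) abort("values must be finite and non-missing")
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  zv <- colnames(m)[sd_ == 0]
  if (length(zv) > 0) {
    abort(sprintf("zero-variance feature(s): %s", paste(zv, collapse = ", ")))
  }
  as_abund_tbl(sweep(sweep(m, 2, mu), 2, sqrt(sd_), "/"), state = "transformed")
}
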