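# Spearman association between two feature sets (taxa vs taxa, taxa vs
# metabolites) with Benjamini-Hochberg correction, exported as an edge list.

#' Spearman correlation matrix between two feature tables
#'
#' Computes Spearman's rho on mid-ranks for every (feature of `x`, feature of
#' `y`) pair, with a two-sided p-value from the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` and optional Benjamini–Hochberg adjustment
#' across all pairs. When `y` is omitted (or shares the identical feature
#' set), each unordered pair is reported once and self-pairs are dropped.
#' Constant features have undefined rank correlation: their pairs are
#' reported with `NA` rho, excluded from the BH family, and flagged with a
#' warning.
#'
#' @param x,y Tibbles (`sample_id` + numeric feature columns) with identical
#'   sample sets; `y` defaults to `x`. Rows are aligned by `sample_id`.
#' @param threshold Significance threshold for the `kept` flag
#'   (default 0.05).
#' @param adjust If `TRUE` (default) `kept` compares the BH-adjusted p-value
#'   to `threshold`; if `FALSE`, the raw p-value (the "p < 0.05 displayed"
#'   convention).
#' @return Tibble edge list: `feature_a`, `feature_b`, `rho`, `p_value`,
#'   `p_adj`, `kept`.
#' @export
spearman_matrix <- function(x, y = NULL, threshold = 0.05, adjust = TRUE) {
  same_set <- is.null(y)
  mx <- abund_matrix(x)
  my <- if (same_set) mx else abund_matrix(y)
  if (!same_set && identical(sort(rownames(mx)), sort(rownames(my)))) {
    my <- my[rownames(mx), , drop = FALSE]
    same_set <- identical(colnames(mx), colnames(my)) && isTRUE(all.equal(mx, my))
  } else if (!same_set) {
    abort(sprintf(
      "sample sets differ: only in x [%s]; only in y [%s]",
      paste(utils::head(setdiff(rownames(mx), rownames(my)), 5), collapse = ", "),
      paste(utils::head(setdiff(rownames(my), rownames(mx)), 5), collapse = ", ")))
  }
  n <- nrow(mx)
  if (n < 4) abort("need at least 4 shared samples")
  rx <- apply(mx, 2, rank)
  ry <- if (same_set) rx else apply(my, 2, rank)
  const_x <- apply(mx, 2, function(v) length(unique(v)) == 1)
  const_y <- apply(my, 2, function(v) length(unique(v)) == 1)
  if (any(const_x) || any(const_y)) {
    warn(sprintf("constant feature(s) with undefined rank correlation: %s",
                 paste(unique(c(colnames(mx)[const_x], colnames(my)[const_y])),
                       collapse = ", ")))
  }
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[const_x, ] <- NA_real_
  rho[, const_y] <- NA_real_
  pairs <- tidyr::expand_grid(feature_a = colnames(mx), feature_b = colnames(my))
  pairs$rho <- as.vector(t(rho))  # expand_grid varies feature_b fastest
  if (same_set) {
    ia <- match(pairs$feature_a, colnames(mx))
    ib <- match(pairs$feature_b, colnames(my))
    pairs <- pairs[ia < ib, , drop = FALSE]
  }
  r <- pmin(pmax(pairs$rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  pairs$p_value <- p
  pairs$p_adj <- NA_real_
  ok <- !is.na(pairs$p_value)
  pairs$p_adj[ok] <- bh_adjust(pairs$p_value[ok])
  crit <- if (adjust) pairs$p_adj else pairs$p_value
  pairs$kept <- !is.na(crit) & crit < threshold
  tibble::as_tibble(pairs)
}

#' Heatmap of a Spearman edge list
#'
#' @param edges Tibble from [spearman_matrix()].
#' @param kept_only Show only pairs passing the significance filter
#'   (default `FALSE`; non-kept cells are blanked when `TRUE`).
#' @return A ggplot tile heatmap of rho.
#' @export
plot_correlation_heatmap <- function(edges, kept_only = FALSE) {
  df <- edges
  if (kept_only) df <- dplyr::filter(df, .data$kept)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_a, y = .data$feature_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
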