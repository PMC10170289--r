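# Nonparametric multi-group comparison machinery: Kruskal-Wallis omnibus,
# Dunn's post-hoc pairwise z tests, Bonferroni / Benjamini-Hochberg
# adjustment. Mid-ranks for ties everywhere; chi-square approximation for KW
# (group sizes in the intended uses are >= 21).

as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least 2 numeric vectors")
  }
  lens <- vapply(groups, length, 1L)
  if (any(lens == 0)) abort("empty group supplied")
  if (!all(vapply(groups, is.numeric, TRUE))) abort("groups must be numeric")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

#' Kruskal–Wallis rank-sum test
#'
#' Omnibus test that k groups come from the same distribution, computed on
#' mid-ranks with the standard tie correction and a chi-square approximation
#' with `k - 1` degrees of freedom. If every pooled observation is identical
#' the statistic is 0 and p = 1.
#'
#' @param groups Named list of numeric vectors, one per group (each with at
#'   least 2 observations).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("every group needs at least 2 observations")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled mid-ranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided p-values,
#' adjusted across all pairs by the requested method.
#'
#' @param groups Named list of numeric vectors (at least 2 groups, each with
#'   at least 2 observations).
#' @param adjustment `"bonferroni"`, `"bh"`, or `"none"`.
#' @return Tibble with one row per unordered pair: `group_a`, `group_b`, `z`,
#'   `p_value`, `adjusted_p`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "bh", "none")) {
  adjustment <- match.arg(adjustment)
  groups <- as_group_list(groups)
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("every group needs at least 2 observations")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  r <- rank(x)  # mid-ranks
  n_tot <- length(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(var_base * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    tibble(group_a = a, group_b = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  res$adjusted_p <- switch(adjustment,
    bonferroni = stats::p.adjust(res$p_value, "bonferroni"),
    bh = stats::p.adjust(res$p_value, "BH"),
    none = res$p_value)
  res
}

#' Benjamini–Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as the input), controlling the false
#'   discovery rate.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
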