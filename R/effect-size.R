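# LEfSe-style discriminatory-feature discovery: a Kruskal-Wallis gate
# followed by a bootstrap one-against-all LDA effect size on a [1, 1e6]
# rescaled abundance scale, reported as log10.

# Discriminant direction for a binary split with a ridge-regularised pooled
# within-class covariance (small bootstrap classes make plain LDA singular).
lda_direction <- function(m, is_target, ridge_frac = 1e-6) {
  m1 <- m[is_target, , drop = FALSE]
  m0 <- m[!is_target, , drop = FALSE]
  dmu <- colMeans(m1) - colMeans(m0)
  sw <- ((nrow(m1) - 1) * stats::cov(m1) + (nrow(m0) - 1) * stats::cov(m0)) /
    (nrow(m1) + nrow(m0) - 2)
  tr <- sum(diag(sw))
  if (tr <= 0) tr <- 1
  sw <- sw + diag(ridge_frac * tr, ncol(m))
  w <- solve(sw, dmu)
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(list(w_unit = w, dmu = dmu))
  list(w_unit = w / nw, dmu = dmu)
}

#' LDA effect size for discriminatory features
#'
#' Identifies features that discriminate between groups in two stages, in the
#' spirit of LEfSe. Stage 1 runs a Kruskal–Wallis test per feature across all
#' groups; features with `p >= kw_alpha` fail the gate. Stage 2 rescales the
#' relative abundances onto `[1, rescale_max]`, and for each group that is the
#' enrichment target of at least one surviving feature, fits a
#' one-against-all linear discriminant on bootstrap subsamples
#' (`n_boot` rounds, a fixed fraction of each class per round, regularised
#' within-class covariance). The per-feature effect size is the log10 of the
#' bootstrap-averaged absolute discriminant difference between class means:
#' `|(dmu_f + w_f * (w . dmu)) / 2|` with `w` the unit discriminant direction
#' and `dmu` the class-mean difference on the rescaled scale.
#'
#' A feature passes when `kw_p < kw_alpha` and `lda_log10 > lda_threshold`.
#'
#' @param data Relative-abundance tibble (`sample_id` + feature columns, rows
#'   summing to 1).
#' @param metadata Tibble with `sample_id`, `group`; at least 2 groups, each
#'   with at least 3 samples.
#' @param kw_alpha Kruskal–Wallis gate level (default 0.05).
#' @param lda_threshold Pass threshold on the log10 effect size (default 2;
#'   some analyses use 3).
#' @param n_boot Bootstrap rounds (default 30).
#' @param subsample_fraction Fraction of each class drawn (without
#'   replacement) per round (default 2/3).
#' @param rescale_max Upper end of the abundance rescaling (default `1e6`).
#' @param seed Integer seed; results are deterministic given
#'   `(seed, n_boot)` and invariant to sample order.
#' @return Tibble with one row per feature: `feature_id`, `kw_p`,
#'   `lda_log10` (`NA` for features failing the gate), `enriched_group`
#'   (group with highest mean relative abundance), `pass`.
#' @export
lda_effect_size <- function(data, metadata, kw_alpha = 0.05,
                            lda_threshold = 2, n_boot = 30,
                            subsample_fraction = 2 / 3,
                            rescale_max = 1e6, seed = 1L) {
  m <- abund_matrix(data)
  grp <- match_groups(rownames(m), metadata)
  if (length(unique(grp)) < 2) abort("need at least 2 groups")
  ns <- table(grp)
  if (any(ns < 3)) {
    abort(sprintf("group(s) with fewer than 3 samples: %s",
                  paste(names(ns)[ns < 3], collapse = ", ")))
  }
  if (!is.numeric(n_boot) || n_boot < 1) abort("`n_boot` must be >= 1")
  # canonical sample order so results are invariant to input order
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  grp <- grp[ord]

  kw_p <- apply(m, 2, function(v) {
    kruskal_wallis(split(v, grp))$p_value
  })
  group_means <- rowsum(m, grp) / as.vector(table(grp))
  enriched <- rownames(group_means)[apply(group_means, 2, which.max)]

  # rescale relative abundances monotonically onto [1, rescale_max]
  ms <- 1 + m * (rescale_max - 1)

  lda_log10 <- rep(NA_real_, ncol(m))
  surv <- which(kw_p < kw_alpha)
  if (length(surv) > 0) {
    withr::with_seed(as.integer(seed), {
      for (target in unique(enriched[surv])) {
        feats <- surv[enriched[surv] == target]
        sub <- ms[, feats, drop = FALSE]
        is_t <- grp == target
        idx_t <- which(is_t); idx_o <- which(!is_t)
        n_t <- max(2L, ceiling(subsample_fraction * length(idx_t)))
        n_o <- max(2L, ceiling(subsample_fraction * length(idx_o)))
        eff <- matrix(0, nrow = n_boot, ncol = length(feats))
        for (b in seq_len(n_boot)) {
          take <- c(sample(idx_t, n_t), sample(idx_o, n_o))
          d <- lda_direction(sub[take, , drop = FALSE], is_t[take])
          proj_diff <- sum(d$w_unit * d$dmu)
          eff[b, ] <- abs((d$dmu + d$w_unit * proj_diff) / 2)
        }
        lda_log10[feats] <- log10(pmax(colMeans(eff), 1))
      }
    })
  }
  tibble(
    feature_id = colnames(m),
    kw_p = unname(kw_p),
    lda_log10 = lda_log10,
    enriched_group = enriched,
    pass = kw_p < kw_alpha & !is.na(lda_log10) & lda_log10 > lda_threshold
  )
}

#' Bar plot of LDA effect sizes
#'
#' @param results Tibble from [lda_effect_size()].
#' @param threshold Vertical reference line (default 2).
#' @return A ggplot of passing features, grouped by enriched group.
#' @export
plot_effect_sizes <- function(results, threshold = 2) {
  df <- dplyr::filter(results, .data$pass)
  df <- dplyr::arrange(df, .data$enriched_group, .data$lda_log10)
  df$feature_id <- factor(df$feature_id, levels = df$feature_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lda_log10, y = .data$feature_id,
                                   fill = .data$enriched_group)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "LDA score (log10)", y = NULL, fill = "enriched in") +
    ggplot2::theme_minimal()
}
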