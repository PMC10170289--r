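# The normobiotic reference model: PCA on healthy-control profiles with
# multivariate statistical process control limits for Hotelling's T-squared
# and the Q statistic (squared prediction error), combined into a Dysbiosis
# Index (DI).

#' Fit a normobiotic PCA reference model on healthy samples
#'
#' Centres (and optionally autoscales) the reference matrix, performs PCA via
#' singular value decomposition, retains the smallest number of components
#' whose cumulative variance reaches `variance_target`, and computes the
#' `(1 - alpha)` control limits used for scoring:
#'
#' * Hotelling's T-squared limit:
#'   `k (n-1)(n+1) / (n (n-k)) * F(1-alpha; k, n-k)` — the new-observation
#'   form, so fresh healthy samples exceed it with probability `alpha`.
#' * Q (squared prediction error) limit: the Jackson–Mudholkar approximation
#'   from the residual eigenvalue moments
#'   `theta_i = sum_(j>k) lambda_j^i`, `h0 = 1 - 2 theta1 theta3 / (3 theta2^2)`,
#'   `q_limit = theta1 * (z(1-alpha) sqrt(2 theta2 h0^2)/theta1 + 1 +
#'   theta2 h0 (h0-1)/theta1^2)^(1/h0)`.
#'
#' If no residual variance exists (full-rank retention), `q_limit = 0` and Q
#' scoring is disabled with a warning.
#'
#' @param reference Transformed abundance tibble of healthy reference samples
#'   (`sample_id` + numeric feature columns), e.g. CLR relative abundances
#'   from [transform_abundance()]. At least 10 samples.
#' @param variance_target Cumulative-variance fraction for choosing the number
#'   of retained components `k` (default 0.90); ties at exactly the target
#'   resolve to the smallest `k`.
#' @param alpha Significance level of both control limits (default 0.05).
#' @param autoscale Divide features by their reference standard deviation
#'   before PCA (default `FALSE`).
#' @param k Optional: force the retained component count instead of using
#'   `variance_target`; must satisfy `1 <= k < min(n - 1, d)`.
#' @return An object of class `normo_ref`: center/scale vectors, orthonormal
#'   loadings (d x k), all eigenvalues, `k`, `n_ref`, `alpha`, `t2_limit`,
#'   `q_limit`, and the locked feature identifiers.
#' @seealso [score_samples()], [tidy.normo_ref()], [glance.normo_ref()]
#' @export
fit_reference_model <- function(reference, variance_target = 0.9,
                                alpha = 0.05, autoscale = FALSE, k = NULL) {
  m <- abund_matrix(reference)
  n <- nrow(m); d <- ncol(m)
  if (n < 10) {
    abort(sprintf("reference model needs at least 10 samples, got %d", n))
  }
  if (anyNA(m)) abort("reference contains missing values")
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
    abort("`variance_target` must be in (0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)")
  }
  center <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  if (sum(sds > 0) < 2) abort("need at least 2 features with nonzero variance")
  scale_ <- if (autoscale) {
    if (any(sds == 0)) {
      abort(sprintf("autoscaling impossible, zero-variance feature(s): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    }
    sds
  } else rep(1, d)
  xs <- sweep(sweep(m, 2, center), 2, scale_, "/")
  sv <- svd(xs)
  lam <- numeric(d)
  lam[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  k_max <- min(n - 2, d - 1)
  if (is.null(k)) {
    cumvar <- cumsum(lam) / sum(lam)
    k <- which(cumvar >= variance_target - 1e-12)[1]
    k <- min(k, k_max)
  } else {
    if (!is.numeric(k) || k < 1 || k > k_max) {
      abort(sprintf("forced `k` must be in [1, %d]", k_max))
    }
    k <- as.integer(k)
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign convention: each column's largest-magnitude entry > 0
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(m)
  t2_limit <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    stats::qf(1 - alpha, k, n - k)
  resid_lam <- lam[seq.int(k + 1, length.out = d - k)]
  th1 <- sum(resid_lam); th2 <- sum(resid_lam^2); th3 <- sum(resid_lam^3)
  if (th1 <= .Machine$double.eps * sum(lam)) {
    warn("no residual variance beyond retained components; Q scoring disabled")
    q_limit <- 0
  } else {
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    z <- stats::qnorm(1 - alpha)
    base <- z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
    q_limit <- th1 * base^(1 / h0)
  }
  structure(list(
    center = center, scale = scale_, loadings = loadings,
    eigenvalues = lam, k = k, n_ref = n, alpha = alpha,
    variance_target = variance_target, autoscale = autoscale,
    t2_limit = t2_limit, q_limit = q_limit,
    feature_ids = colnames(m),
    transform = attr(reference, "transform"),
    pseudocount = attr(reference, "pseudocount")
  ), class = "normo_ref")
}

#' @export
print.normo_ref <- function(x, ...) {
  cat(sprintf(
    "Normobiotic PCA reference model\n  reference samples: %d, features: %d\n  retained components k = %d (variance target %.2f)\n  alpha = %.3g; T2 limit = %.4g; Q limit = %.4g%s\n",
    x$n_ref, length(x$feature_ids), x$k, x$variance_target, x$alpha,
    x$t2_limit, x$q_limit, if (x$q_limit == 0) " (Q disabled)" else ""))
  invisible(x)
}

#' Score samples against a normobiotic reference model
#'
#' Each sample is centred/scaled with the model's parameters, projected onto
#' the retained loadings to give scores `t`, and summarised by
#' `T2 = sum_(i<=k) t_i^2 / lambda_i` (Mahalanobis distance in score space)
#' and `Q = ||x - reconstruction||^2` (squared prediction error). The
#' Dysbiosis Index combines both relative to their control limits; with the
#' default `combine = "mean"`, `DI = (T2/t2_limit + Q/q_limit)/2`, so DI > 1
#' means the sample exceeds the normobiotic confidence range on average.
#'
#' @param model A fitted [fit_reference_model()] object.
#' @param samples Transformed abundance tibble whose features match the
#'   model's exactly (any order; a mismatch is an error listing the
#'   difference).
#' @param combine How to combine the two normalised statistics into DI:
#'   `"mean"` (default), `"max"`, `"t2"` (T-squared only) or `"q"`.
#' @return A `di_scores` tibble: `sample_id`, `t2`, `q`, `di`, `outside_t2`,
#'   `outside_q` (limit-exceedance flags).
#' @export
score_samples <- function(model, samples,
                          combine = c("mean", "max", "t2", "q")) {
  combine <- match.arg(combine)
  if (!inherits(model, "normo_ref")) abort("`model` must be a normo_ref object")
  m <- abund_matrix(samples)
  extra <- setdiff(colnames(m), model$feature_ids)
  missing <- setdiff(model$feature_ids, colnames(m))
  if (length(extra) > 0 || length(missing) > 0) {
    abort(sprintf(
      "feature mismatch with model: missing [%s]; unexpected [%s]",
      paste(utils::head(missing, 10), collapse = ", "),
      paste(utils::head(extra, 10), collapse = ", ")))
  }
  m <- m[, model$feature_ids, drop = FALSE]
  xs <- sweep(sweep(m, 2, model$center), 2, model$scale, "/")
  scores <- xs %*% model$loadings
  lam_k <- model$eigenvalues[seq_len(model$k)]
  t2 <- as.vector(scores^2 %*% (1 / lam_k))
  resid <- xs - scores %*% t(model$loadings)
  q <- unname(rowSums(resid^2))
  q_on <- model$q_limit > 0
  if (combine == "q" && !q_on) abort("Q scoring is disabled for this model")
  di <- switch(combine,
    mean = if (q_on) (t2 / model$t2_limit + q / model$q_limit) / 2
           else t2 / model$t2_limit,
    max  = if (q_on) pmax(t2 / model$t2_limit, q / model$q_limit)
           else t2 / model$t2_limit,
    t2   = t2 / model$t2_limit,
    q    = q / model$q_limit)
  out <- tibble(
    sample_id = rownames(m), t2 = t2, q = q, di = di,
    outside_t2 = t2 > model$t2_limit,
    outside_q = if (q_on) q > model$q_limit else NA
  )
  attr(out, "t2_limit") <- model$t2_limit
  attr(out, "q_limit") <- model$q_limit
  attr(out, "alpha") <- model$alpha
  class(out) <- c("di_scores", class(out))
  out
}

#' Compare Dysbiosis Index distributions between groups
#'
#' Runs the Kruskal–Wallis omnibus test and Dunn's post-hoc pairwise
#' comparisons on per-sample DI values split by group label.
#'
#' @param scores A `di_scores` tibble from [score_samples()] (or any tibble
#'   with `sample_id` and `di` columns).
#' @param metadata Tibble with `sample_id` and `group`; every scored sample
#'   must be present.
#' @param adjustment P-value adjustment for the pairwise comparisons:
#'   `"bonferroni"` (default), `"bh"`, or `"none"`.
#' @return A list with `overall` (one-row tibble: `statistic`, `df`,
#'   `p_value`) and `pairwise` (tibble: `group_a`, `group_b`, `z`, `p_value`,
#'   `adjusted_p`).
#' @export
di_between_groups <- function(scores, metadata,
                              adjustment = c("bonferroni", "bh", "none")) {
  adjustment <- match.arg(adjustment)
  if (!all(c("sample_id", "di") %in% names(scores))) {
    abort("`scores` must have `sample_id` and `di` columns")
  }
  grp <- match_groups(scores$sample_id, metadata)
  groups <- split(scores$di, grp)
  small <- names(groups)[vapply(groups, length, 1L) < 2]
  if (length(small) > 0) {
    abort(sprintf("group(s) with fewer than 2 samples: %s",
                  paste(small, collapse = ", ")))
  }
  list(
    overall = kruskal_wallis(groups),
    pairwise = dunn_posthoc(groups, adjustment = adjustment)
  )
}

#' Tidy a normobiotic reference model into per-component rows
#'
#' @param x A `normo_ref` object.
#' @param ... Unused.
#' @return Tibble with one row per principal component: `component`,
#'   `eigenvalue`, `prop_variance`, `cum_variance`, `retained`.
#' @method tidy normo_ref
#' @export
tidy.normo_ref <- function(x, ...) {
  lam <- x$eigenvalues
  tibble(
    component = seq_along(lam),
    eigenvalue = lam,
    prop_variance = lam / sum(lam),
    cum_variance = cumsum(lam) / sum(lam),
    retained = seq_along(lam) <= x$k
  )
}

#' One-row summary of a normobiotic reference model
#'
#' @param x A `normo_ref` object.
#' @param ... Unused.
#' @return One-row tibble: `n_ref`, `n_features`, `k`, `variance_explained`,
#'   `alpha`, `t2_limit`, `q_limit`.
#' @method glance normo_ref
#' @export
glance.normo_ref <- function(x, ...) {
  tibble(
    n_ref = x$n_ref, n_features = length(x$feature_ids), k = x$k,
    variance_explained = sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues),
    alpha = x$alpha, t2_limit = x$t2_limit, q_limit = x$q_limit
  )
}

#' Scree plot of a reference model
#'
#' @param object A `normo_ref` object.
#' @param ... Unused.
#' @return A ggplot: per-component variance fraction with the retained
#'   components highlighted.
#' @method autoplot normo_ref
#' @export
autoplot.normo_ref <- function(object, ...) {
  td <- tidy.normo_ref(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$prop_variance,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_variance), linewidth = 0.4,
                       inherit.aes = FALSE,
                       mapping = ggplot2::aes(x = .data$component,
                                              y = .data$cum_variance)) +
    ggplot2::labs(x = "principal component", y = "variance fraction",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' Control-chart plot of DI scores
#'
#' Scatter of T-squared versus Q with the model's control limits; samples
#' outside either limit exceed the normobiotic confidence range.
#'
#' @param object A `di_scores` tibble from [score_samples()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot di_scores
#' @export
autoplot.di_scores <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t2, y = .data$q,
                                    colour = .data$di)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "t2_limit"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Hotelling's T²", y = "Q (squared prediction error)",
                  colour = "DI") +
    ggplot2::theme_minimal()
  if (isTRUE(attr(object, "q_limit") > 0)) {
    p <- p + ggplot2::geom_hline(yintercept = attr(object, "q_limit"),
                                 linetype = "dashed")
  }
  p
}

#' Boxplot of DI by group
#'
#' @param scores `di_scores` tibble.
#' @param metadata Tibble with `sample_id`, `group`.
#' @return A ggplot object (DI on log scale, dashed line at DI = 1).
#' @export
plot_di_by_group <- function(scores, metadata) {
  df <- tibble::as_tibble(scores)
  df$group <- match_groups(df$sample_id, metadata)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$di,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Dysbiosis Index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write a reference model to a plain-text file
#'
#' Plain-text format: `key<TAB>value` header lines, then a tab-separated
#' block with one row per feature (center, scale, loadings) and a final
#' eigenvalue block. [read_reference_model()] reads it back losslessly.
#'
#' @param model `normo_ref` object.
#' @param path Output path.
#' @return `model`, invisibly.
#' @export
write_reference_model <- function(model, path) {
  if (!inherits(model, "normo_ref")) abort("`model` must be a normo_ref object")
  hdr <- c(
    sprintf("#k\t%d", model$k),
    sprintf("#n_ref\t%d", model$n_ref),
    sprintf("#alpha\t%s", format(model$alpha, digits = 17)),
    sprintf("#variance_target\t%s", format(model$variance_target, digits = 17)),
    sprintf("#autoscale\t%s", model$autoscale),
    sprintf("#t2_limit\t%s", format(model$t2_limit, digits = 17)),
    sprintf("#q_limit\t%s", format(model$q_limit, digits = 17)),
    sprintf("#transform\t%s", model$transform %||% "none"),
    sprintf("#pseudocount\t%s",
            if (is.null(model$pseudocount)) "none"
            else format(model$pseudocount, digits = 17)),
    sprintf("#eigenvalues\t%s",
            paste(format(model$eigenvalues, digits = 17, trim = TRUE),
                  collapse = "\t"))
  )
  body <- tibble(feature_id = model$feature_ids,
                 center = model$center, scale = model$scale)
  ld <- as_tibble(model$loadings, .name_repair = ~ paste0("pc", seq_len(model$k)))
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(dplyr::bind_cols(body, ld), path,
                                    append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(model)
}

#' Read a reference model written by [write_reference_model()]
#'
#' @param path Model file path.
#' @return A `normo_ref` object.
#' @export
read_reference_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr_lines <- lines[startsWith(lines, "#")]
  hdr <- strsplit(sub("^#", "", hdr_lines), "\t")
  keys <- vapply(hdr, `[`, "", 1)
  val <- function(key) hdr[[match(key, keys)]][-1]
  body <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                          col_types = readr::cols(
                            feature_id = readr::col_character(),
                            .default = readr::col_double()),
                          progress = FALSE, show_col_types = FALSE)
  k <- as.integer(val("k"))
  loadings <- as.matrix(body[paste0("pc", seq_len(k))])
  rownames(loadings) <- body$feature_id
  pc <- val("pseudocount")
  tr <- val("transform")
  structure(list(
    center = stats::setNames(body$center, body$feature_id),
    scale = stats::setNames(body$scale, body$feature_id),
    loadings = loadings,
    eigenvalues = as.numeric(val("eigenvalues")),
    k = k,
    n_ref = as.integer(val("n_ref")),
    alpha = as.numeric(val("alpha")),
    variance_target = as.numeric(val("variance_target")),
    autoscale = as.logical(val("autoscale")),
    t2_limit = as.numeric(val("t2_limit")),
    q_limit = as.numeric(val("q_limit")),
    feature_ids = body$feature_id,
    transform = if (identical(tr, "none")) NULL else tr,
    pseudocount = if (identical(pc, "none")) NULL else as.numeric(pc)
  ), class = "normo_ref")
}
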