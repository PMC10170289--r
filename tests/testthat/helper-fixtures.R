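# Fixtures are built in code; no files are shipped.

# tibble from a matrix with sample/feature ids
tbl_from_matrix <- function(m, prefix_s = "s", prefix_f = "f") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("%s%03d", prefix_s, seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("%s%03d", prefix_f, seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# seeded random count table
rand_count_table <- function(n, d, seed, lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * d, lambda), nrow = n)
    tbl_from_matrix(m)
  })
}

# samples from a diagonal-covariance multivariate normal
mvn_table <- function(n, d, seed, vars = NULL, mean = 0) {
  if (is.null(vars)) vars <- 2 * 0.8^(seq_len(d) - 1)
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * d, sd = rep(sqrt(vars), each = n)), nrow = n) + mean
    tbl_from_matrix(m, prefix_s = "mv")
  })
}

# two-group relative-abundance table with one fold-change-shifted feature
two_group_rel_table <- function(n_per_group = 30, d = 200, fold = 4,
                                shifted = 1, sdlog = 0.3, seed = 1) {
  withr::with_seed(seed, {
    base <- exp(stats::rnorm(d, 0, 1.5))
    m <- matrix(stats::rlnorm(2 * n_per_group * d,
                              meanlog = rep(log(base), each = 2 * n_per_group),
                              sdlog = sdlog), nrow = 2 * n_per_group)
    m[seq(n_per_group + 1, 2 * n_per_group), shifted] <-
      m[seq(n_per_group + 1, 2 * n_per_group), shifted] * fold
    tbl_from_matrix(m / rowSums(m))
  })
}

two_group_metadata <- function(n_per_group = 30) {
  tibble::tibble(sample_id = sprintf("s%03d", seq_len(2 * n_per_group)),
                 group = rep(c("A", "B"), each = n_per_group))
}

# independent tie-corrected Kruskal-Wallis H via the direct rank-sum formula
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_tot <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rsum <- tapply(r, idx, sum)
  ns <- vapply(groups, length, 1L)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rsum^2 / ns) - 3 * (n_tot + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n_tot^3 - n_tot))
}

# brute-force Benjamini-Hochberg step-up: min over the tail of m*p/rank
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    adj[i] <- min(1, min(m * p[ord][rank_i:m] / (rank_i:m)))
  }
  adj
}

# brute-force T2/Q: explicit per-sample projection loop
t2_q_oracle <- function(model, samples_tbl) {
  m <- as.matrix(samples_tbl[setdiff(names(samples_tbl), "sample_id")])
  m <- m[, model$feature_ids, drop = FALSE]
  t2 <- q <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- (m[i, ] - model$center) / model$scale
    t_i <- drop(crossprod(model$loadings, x))
    t2[i] <- sum(t_i^2 / model$eigenvalues[seq_len(model$k)])
    q[i] <- sum((x - drop(model$loadings %*% t_i))^2)
  }
  list(t2 = t2, q = q)
}
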