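test_that("PCA eigenvalues match an independent covariance eigendecomposition", {
  tb <- mvn_table(50, 20, seed = 31)
  model <- fit_reference_model(tb, variance_target = 0.9)
  m <- as.matrix(tb[-1])
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model$eigenvalues, ev, tolerance = 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  # loadings orthonormal
  g <- crossprod(model$loadings)
  expect_equal(g, diag(model$k), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the T2 limit equals the F-quantile formula and k selection behaves", {
  tb <- mvn_table(50, 20, seed = 32)
  model <- fit_reference_model(tb, k = 2, alpha = 0.05)
  n <- 50; k <- 2
  expect_equal(model$t2_limit,
               k * (n - 1) * (n + 1) / (n * (n - k)) * qf(0.95, k, n - k),
               tolerance = 1e-12)

  # one feature carrying (essentially) all variance forces k = 1
  m <- withr::with_seed(33, cbind(rnorm(30, sd = 100),
                                  matrix(rnorm(30 * 4, sd = 1e-4), 30)))
  forced <- fit_reference_model(tbl_from_matrix(m), variance_target = 0.5)
  expect_equal(forced$k, 1L)
  f2 <- fit_reference_model(tbl_from_matrix(m), variance_target = 1 - 1e-13)
  expect_lte(f2$k, min(30 - 2, 5 - 1))

  expect_error(fit_reference_model(mvn_table(5, 8, seed = 1)), "at least 10")
  expect_error(fit_reference_model(tb, k = 100), "forced `k`")
})

test_that("T2 and Q match a brute-force projection oracle and the centroid scores zero", {
  ref <- mvn_table(60, 15, seed = 41)
  model <- fit_reference_model(ref, variance_target = 0.8)
  new <- mvn_table(25, 15, seed = 42)
  names(new) <- names(ref)
  sc <- score_samples(model, new)
  oracle <- t2_q_oracle(model, new)
  expect_equal(sc$t2, oracle$t2, tolerance = 1e-8)
  expect_equal(sc$q, oracle$q, tolerance = 1e-8)
  expect_true(all(sc$t2 >= 0 & sc$q >= 0 & sc$di >= 0))
  expect_equal(sc$outside_t2, sc$t2 > model$t2_limit)
  expect_equal(sc$outside_q, sc$q > model$q_limit)

  centroid <- tbl_from_matrix(matrix(model$center, nrow = 1,
                                     dimnames = list("c0", model$feature_ids)))
  names(centroid) <- names(ref)
  sc0 <- score_samples(model, centroid)
  expect_equal(sc0$t2, 0, tolerance = 1e-16)
  expect_equal(sc0$q, 0, tolerance = 1e-16)
  expect_equal(sc0$di, 0, tolerance = 1e-16)
})

test_that("scaling a deviation by c multiplies T2 by c^2 and never lowers Q", {
  ref <- mvn_table(40, 10, seed = 51)
  model <- fit_reference_model(ref, variance_target = 0.7)
  x <- as.matrix(mvn_table(1, 10, seed = 52)[-1])
  for (c_ in c(1.5, 2, 5)) {
    xs <- tbl_from_matrix(rbind(model$center + (x - model$center),
                                model$center + c_ * (x - model$center)))
    names(xs) <- c("sample_id", model$feature_ids)
    sc <- score_samples(model, xs)
    expect_equal(sc$t2[2], c_^2 * sc$t2[1], tolerance = 1e-10)
    expect_gte(sc$q[2], sc$q[1])
  }
})

test_that("T2 and Q are invariant under a consistent feature permutation", {
  ref <- mvn_table(40, 12, seed = 61)
  model <- fit_reference_model(ref, variance_target = 0.85)
  new <- mvn_table(10, 12, seed = 62)
  names(new) <- names(ref)
  perm <- withr::with_seed(63, sample(12))
  ref_p <- ref[c(1, perm + 1)]
  new_p <- new[c(1, perm + 1)]
  model_p <- fit_reference_model(ref_p, variance_target = 0.85)
  sc <- score_samples(model, new)
  sc_p <- score_samples(model_p, new_p)
  expect_equal(sc$t2, sc_p$t2, tolerance = 1e-8)
  expect_equal(sc$q, sc_p$q, tolerance = 1e-8)
})

test_that("rank-deficient data with full retained rank gives Q = 0 and disables the Q limit", {
  # data living exactly in a 5-dimensional subspace of 10 features
  m <- withr::with_seed(71, {
    z <- matrix(rnorm(30 * 5), 30)
    b <- matrix(rnorm(5 * 10), 5)
    z %*% b
  })
  tb <- tbl_from_matrix(m)
  expect_warning(model <- fit_reference_model(tb, variance_target = 1),
                 "Q scoring disabled")
  expect_equal(model$k, 5L)
  expect_equal(model$q_limit, 0)
  sc <- score_samples(model, tb)
  expect_true(all(abs(sc$q) < 1e-8))
  expect_equal(sc$di, sc$t2 / model$t2_limit)
  expect_true(all(is.na(sc$outside_q)))
  expect_error(score_samples(model, tb, combine = "q"), "disabled")
})

test_that("scoring rejects feature mismatches and reindexes by name", {
  ref <- mvn_table(30, 6, seed = 81)
  model <- fit_reference_model(ref, variance_target = 0.9)
  new <- mvn_table(5, 6, seed = 82)
  names(new) <- names(ref)
  shuffled <- new[c(1, 4, 2, 7, 3, 5, 6)]
  expect_equal(score_samples(model, shuffled)$t2, score_samples(model, new)$t2)
  bad <- new; names(bad)[2] <- "other_feature"
  expect_error(score_samples(model, bad), "feature mismatch.*f001.*other_feature")
})

test_that("the model file round-trips through plain text", {
  rel <- to_relative_abundance(rand_count_table(20, 15, seed = 91))
  tr <- transform_abundance(rel, "clr")
  model <- fit_reference_model(tr, variance_target = 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_model(model, path)
  back <- read_reference_model(path)
  for (fld in c("center", "scale", "eigenvalues", "k", "n_ref", "alpha",
                "t2_limit", "q_limit", "feature_ids", "transform",
                "pseudocount", "autoscale", "variance_target")) {
    expect_equal(back[[fld]], model[[fld]], ignore_attr = TRUE, label = fld)
  }
  expect_equal(unname(back$loadings), unname(model$loadings))
  # scores computed from the reread model are identical
  sc1 <- score_samples(model, tr)
  sc2 <- score_samples(back, tr)
  expect_equal(sc2$di, sc1$di)
})

test_that("tidy/glance summarise the model consistently", {
  tb <- mvn_table(30, 8, seed = 101)
  model <- fit_reference_model(tb, variance_target = 0.9)
  td <- tidy(model)
  expect_equal(nrow(td), 8)
  expect_equal(sum(td$retained), model$k)
  expect_equal(td$cum_variance[8], 1)
  gl <- glance(model)
  expect_equal(gl$k, model$k)
  expect_gte(gl$variance_explained, 0.9 - 1e-12)
})

test_that("di_between_groups composes the group-stats operations", {
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                           di = c(1:4 / 10, 2:5 / 10, 6:9 / 10))
  md <- tibble::tibble(sample_id = scores$sample_id,
                       group = rep(c("a", "b", "c"), each = 4))
  res <- di_between_groups(scores, md)
  direct_kw <- kruskal_wallis(split(scores$di, md$group))
  direct_dunn <- dunn_posthoc(split(scores$di, md$group), "bonferroni")
  expect_equal(res$overall, direct_kw)
  expect_equal(res$pairwise, direct_dunn)

  same <- tibble::tibble(sample_id = md$sample_id, di = rep(c(1, 2, 3, 4), 3))
  res0 <- di_between_groups(same, md)
  expect_equal(res0$overall$statistic, 0)
  expect_equal(res0$overall$p_value, 1)

  md_small <- md; md_small$group[md_small$group == "c"] <- c("c", "d", "d", "d")
  expect_error(di_between_groups(same, md_small), "fewer than 2")
})
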