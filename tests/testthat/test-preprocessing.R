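test_that("relative-abundance closure is correct, idempotent and scale-invariant", {
  tb <- tbl_from_matrix(matrix(c(2, 2, 4), nrow = 1))
  rel <- to_relative_abundance(tb)
  expect_equal(unlist(rel[-1], use.names = FALSE), c(0.25, 0.25, 0.5))

  expect_equal(to_relative_abundance(rel), rel)

  counts <- rand_count_table(20, 50, seed = 7)
  rel1 <- to_relative_abundance(counts)
  expect_true(all(abs(rowSums(as.matrix(rel1[-1])) - 1) < 1e-9))

  scaled <- counts
  scaled[-1] <- scaled[-1] * withr::with_seed(8, runif(20, 1, 10))
  expect_equal(as.matrix(to_relative_abundance(scaled)[-1]),
               as.matrix(rel1[-1]))

  zero <- tbl_from_matrix(matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE))
  expect_error(to_relative_abundance(zero), "all-zero sample.*s002")
})

test_that("minimum-value imputation follows the retention rule and never touches observed cells", {
  m <- matrix(c(1, NA, 3, 5,
                2, 5, 8, 1,
                NA, NA, 9, 7), ncol = 3)
  colnames(m) <- c("f1", "f2", "f3")
  tb <- tbl_from_matrix(m)
  out <- min_impute(tb, max_missing_fraction = 1)
  expect_equal(out$f1, c(1, 1, 3, 5))   # NA -> column minimum
  expect_equal(out$f2, c(2, 5, 8, 1))   # observed untouched
  expect_equal(out$f3, c(7, 7, 9, 7))

  # feature missing in 50% of samples dropped at max_missing_fraction = 0.25;
  # a feature missing in exactly 25% is retained
  out2 <- suppressMessages(min_impute(tb, max_missing_fraction = 0.25))
  expect_false("f3" %in% names(out2))
  expect_true(all(c("f1", "f2") %in% names(out2)))

  # no missing cells -> identity
  full <- rand_count_table(5, 4, seed = 2)
  expect_equal(min_impute(full), full, ignore_attr = TRUE)

  all_na <- tbl_from_matrix(matrix(NA_real_, 3, 1))
  expect_error(min_impute(all_na, max_missing_fraction = 1), "no minimum")
})

test_that("prevalence filter matches a brute-force scan and keeps feature order", {
  rel <- to_relative_abundance(rand_count_table(10, 30, seed = 9, lambda = 0.5))
  m <- as.matrix(rel[-1])
  for (thr in c(0, 0.2, 0.5)) {
    kept <- names(rel)[-1][vapply(seq_len(ncol(m)),
                                  function(j) sum(m[, j] > 0) / nrow(m) >= thr,
                                  TRUE)]
    out <- prevalence_filter(rel, min_prevalence = thr)
    expect_equal(names(out)[-1], kept)
  }
  expect_equal(prevalence_filter(rel, 0), rel)
  expect_error(prevalence_filter(rel, 1), "removed every feature")
})

test_that("clr satisfies its identities and matches a two-pass computation", {
  rel <- to_relative_abundance(rand_count_table(15, 20, seed = 4))
  out <- transform_abundance(rel, "clr", pseudocount = 1e-6)
  m <- as.matrix(out[-1])
  expect_true(all(abs(rowSums(m)) < 1e-9))

  # uniform row -> all zeros
  unif <- tbl_from_matrix(matrix(rep(0.25, 4), nrow = 1))
  out_u <- transform_abundance(unif, "clr", pseudocount = 0.01)
  expect_true(all(abs(as.matrix(out_u[-1])) < 1e-12))

  # independent two-pass oracle
  raw <- as.matrix(rel[-1])
  lg <- log(raw + 1e-6)
  oracle <- lg - rowMeans(lg)
  expect_equal(m, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # log-relative is the plain elementwise log
  lr <- transform_abundance(rel, "log-relative", pseudocount = 1e-6)
  expect_equal(as.matrix(lr[-1]), lg, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(transform_abundance(rel, "clr", pseudocount = 0), "positive")
  expect_error(transform_abundance(rand_count_table(3, 3, seed = 1), "clr"),
               "sum to 1")
})

test_that("log2 z-scores and Pareto scaling match hand arithmetic and column-moment oracles", {
  tb <- tbl_from_matrix(matrix(c(2, 4, 8), ncol = 1))
  z <- log2_zscore(tb)
  expect_equal(z[[2]], c(-1, 0, 1))  # log2 -> (1,2,3), sample sd = 1

  pos <- rand_count_table(12, 6, seed = 3)
  pos[-1] <- pos[-1] + 1
  zz <- as.matrix(log2_zscore(pos)[-1])
  expect_true(all(abs(colMeans(zz)) < 1e-9))
  expect_true(all(abs(apply(zz, 2, sd) - 1) < 1e-9))

  const <- tbl_from_matrix(cbind(c(1, 2, 4), c(3, 3, 3)))
  expect_error(log2_zscore(const), "zero-variance.*f002")

  # pareto: sd = 1 feature reduces to centering; sd = 4 scaled by 2
  m <- cbind(a = c(0, 1, 2) * sqrt(1),          # sd 1
             b = c(0, 4, 8))                    # sd 4
  pt <- pareto_scale(tbl_from_matrix(m))
  expect_equal(pt[[2]], c(0, 1, 2) - 1)
  expect_equal(pt[[3]], (c(0, 4, 8) - 4) / 2)

  # brute-force per-column oracle on a seeded table
  mm <- as.matrix(pos[-1])
  oracle <- sweep(sweep(mm, 2, colMeans(mm)), 2, sqrt(apply(mm, 2, sd)), "/")
  expect_equal(as.matrix(pareto_scale(pos)[-1]), oracle,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("transforms are permutation-equivariant in features and samples", {
  rel <- to_relative_abundance(rand_count_table(10, 8, seed = 21))
  perm_f <- withr::with_seed(5, c(1, sample(2:9)))
  perm_s <- withr::with_seed(6, sample(10))
  shuffled <- rel[perm_s, perm_f]
  for (f in list(function(x) transform_abundance(x, "clr", pseudocount = 1e-4),
                 function(x) pareto_scale(x))) {
    a <- f(rel)[perm_s, perm_f]
    b <- f(shuffled)
    expect_equal(as.matrix(a[-1]), as.matrix(b[-1]), ignore_attr = TRUE)
  }
})
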