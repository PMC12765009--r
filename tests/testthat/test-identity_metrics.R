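test_that("one-way sums-of-squares decomposition matches hand ANOVA", {
  a <- anova_decomposition(c(0, 2, 4, 6), c("A", "A", "B", "B"))
  expect_equal(a$ss_total, 20)
  expect_equal(a$ss_within, 4)
  expect_equal(a$ss_among, 16)
  expect_equal(a$f, 8)
  expect_equal(a$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(a$p, 0.1056, tolerance = 1e-3)

  b <- anova_decomposition(c(0, 2, 0, 2), c("A", "A", "B", "B"))
  expect_equal(b$ss_among, 0)
  expect_equal(b$f, 0)

  d <- anova_decomposition(rep(1, 4), c("A", "A", "B", "B"))
  expect_true(d$degenerate)

  expect_error(anova_decomposition(1:3, c("A", "A", "B")), "< 2 calls")
})

test_that("Beecher's statistic follows the sums-of-squares ratio", {
  x <- matrix(c(0, 2, 4, 6), ncol = 1)
  lab <- c("A", "A", "B", "B")
  hs <- calc_hs(x, lab, variant = "all")
  expect_equal(hs$per_component_hs, 0.5 * log2(20 / 4), tolerance = 1e-12)
  expect_equal(hs$hs_all, 1.1610, tolerance = 1e-4)

  hs0 <- calc_hs(matrix(c(0, 2, 0, 2), ncol = 1), lab, variant = "all")
  expect_equal(hs0$hs_all, 0)

  expect_error(calc_hs(matrix(c(1, 1, 5, 5), ncol = 1), lab),
               "zero within-individual")

  # monotonicity: fixed ss_within, growing separation raises HS
  seps <- c(2, 4, 8, 16)
  hs_vals <- sapply(seps, function(s) {
    calc_hs(matrix(c(0, 2, s, s + 2), ncol = 1), lab,
            variant = "all")$hs_all
  })
  expect_true(all(diff(hs_vals) > 0))

  # the mean-square estimator differs only through the df correction
  hs_ms <- calc_hs(x, lab, variant = "all", estimator = "ms_ratio")
  expect_equal(hs_ms$hs_all, 0.5 * log2((20 / 3) / (4 / 2)),
               tolerance = 1e-12)
})

test_that("signature capacity is the floor of 2^HS", {
  pairs <- list(c(6.38, 83), c(4.96, 31), c(5.29, 39), c(3.98, 15))
  for (p in pairs) {
    expect_equal(signatures_from_hs(p[1]), p[2])
  }
  expect_equal(signatures_from_hs(0), 1)
  expect_error(signatures_from_hs(-0.1), "non-negative")
})

test_that("IVS is the chance-corrected discrimination score", {
  expect_equal(calc_ivs(87.7, 22), 19.29)
  expect_equal(calc_ivs(79.4, 22), 17.47)
  expect_equal(calc_ivs(87.5, 14), 12.25)
  expect_equal(calc_ivs(78.9, 10), 7.89)
  expect_equal(calc_ivs(100, 10), 10)
  expect_error(calc_ivs(50, 1), ">= 2")
  expect_error(calc_ivs(120, 10), "\\[0, 100\\]")
})

test_that("leave-one-out LDA matches a hand-rolled discriminant oracle", {
  set.seed(31)
  k <- 3
  n <- 6
  mus <- matrix(c(0, 0, 3, 0, 0, 3), k, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n * 2, sd = 1.2), n, 2), 2, mus[i, ], "+")))
  lab <- rep(c("a", "b", "c"), each = n)

  ds <- calc_ds(x, lab)
  expect_equal(ds$ds_percent, loo_lda_percent(x, lab), tolerance = 1e-9)
  expect_equal(sum(ds$confusion), length(lab))
  expect_equal(unname(rowSums(ds$confusion)), rep(n, k))

  ds_u <- calc_ds(x, lab, priors = "uniform")
  expect_equal(ds_u$ds_percent,
               loo_lda_percent(x, lab, uniform_priors = TRUE),
               tolerance = 1e-9)
})

test_that("well-separated individuals are classified perfectly", {
  set.seed(32)
  x <- rbind(matrix(rnorm(20, sd = 1), 10, 2),
             matrix(rnorm(20, sd = 1), 10, 2) + 100)
  lab <- rep(c("a", "b"), each = 10)
  ds <- calc_ds(x, lab)
  expect_equal(ds$ds_percent, 100)
  expect_equal(ds$ivs, 2)
})

test_that("WID and BID are centroid distances, invariant to rotation", {
  x <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  wid <- calc_wid(x, c("a", "a"))
  expect_equal(wid$wid, 1)

  wid0 <- calc_wid(matrix(1, 4, 3), rep(c("a", "b"), each = 2))
  expect_equal(wid0$wid, c(0, 0))

  b <- calc_bid(matrix(c(0, 2, 4, 6), ncol = 1), c("A", "A", "B", "B"))
  expect_equal(b$bid, c(2, 2))
  expect_equal(calc_bid(matrix(rnorm(6), 3, 2), rep("a", 3))$bid, 0,
               tolerance = 1e-12)

  set.seed(33)
  x <- matrix(rnorm(40 * 5), 40, 5)
  lab <- rep(sprintf("m%d", 1:8), each = 5)
  q <- random_orthogonal(5)
  expect_equal(calc_wid(x, lab)$wid, calc_wid(x %*% q, lab)$wid,
               tolerance = 1e-8)
  expect_equal(calc_bid(x, lab)$bid, calc_bid(x %*% q, lab)$bid,
               tolerance = 1e-8)

  expect_warning(calc_wid(x[-(1:4), , drop = FALSE], lab[-(1:4)]),
                 "skipping")
})

test_that("distance metrics are identical on standardized features and PC scores", {
  tab <- as_call_table(tiny_call_table(4, 6, shift = 40))
  z <- standardize_features(feature_matrix(tab))
  pcs <- pca_scores(z)
  lab <- tab$individual_id
  expect_equal(calc_wid(z, lab)$wid, calc_wid(pcs$scores, lab)$wid,
               tolerance = 1e-8)
  expect_equal(calc_bid(z, lab)$bid, calc_bid(pcs$scores, lab)$bid,
               tolerance = 1e-8)
})
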