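test_that("niche posterior draws are seeded, proper and consistent", {
  set.seed(41)
  x <- rmvn(200, c(1, -2), matrix(c(2, 0.5, 0.5, 1), 2))
  p1 <- fit_niche_posterior(x, n_draws = 400, seed = 7)
  p2 <- fit_niche_posterior(x, n_draws = 400, seed = 7)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$sigma, p2$sigma)

  # posterior mean of the mean close to the truth (3 standard errors)
  se <- sqrt(diag(cov(x)) / nrow(x))
  expect_true(all(abs(colMeans(p1$mu) - c(1, -2)) < 3 * se))
  # posterior mean of the covariance near the sample covariance
  expect_equal(apply(p1$sigma, 1:2, mean), cov(x), tolerance = 0.15)

  # 1-D: every covariance draw strictly positive
  suppressWarnings(p1d <- fit_niche_posterior(matrix(c(0, 2), 2, 1),
                                              n_draws = 100, seed = 1))
  expect_true(all(p1d$sigma > 0))

  expect_error(fit_niche_posterior(matrix(1:2, 1, 2)), ">= 2 calls")
  expect_error(fit_niche_posterior(matrix(rnorm(6), 2, 3)), "more calls")
})

test_that("region membership is a chi-square Mahalanobis threshold", {
  expect_true(region_membership(c(0, 0), c(0, 0), diag(2), alpha = 0.5))
  # 1-D boundary at sqrt(qchisq(0.99, 1)) = 2.5758
  expect_true(region_membership(2.575, 0, matrix(1), alpha = 0.99))
  expect_false(region_membership(2.577, 0, matrix(1), alpha = 0.99))

  # invariance under simultaneous affine transformation
  set.seed(42)
  mu <- c(1, 2, 3)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  pts <- rmvn(50, mu, S)
  A <- matrix(rnorm(9), 3)
  b <- rnorm(3)
  expect_identical(
    region_membership(pts, mu, S, 0.9),
    region_membership(sweep(pts %*% t(A), 2, b, "+"), drop(A %*% mu + b),
                      A %*% S %*% t(A), 0.9))

  expect_error(region_membership(c(1, 2), c(0, 0, 0), diag(3)), "mismatch")
})

test_that("pairwise overlap behaves in the separation and coincidence limits", {
  set.seed(43)
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  xa <- rmvn(60, c(0, 0), S)
  pa <- fit_niche_posterior(xa, n_draws = 400, seed = 1)
  pfar <- fit_niche_posterior(rmvn(60, c(100, 100), S),
                              n_draws = 400, seed = 2)
  expect_lt(pairwise_overlap(pa, pfar, n_mc = 2000, seed = 3), 1e-3)

  # monotone decrease of overlap along a separation grid
  seps <- c(0, 1.5, 3, 6)
  ovs <- sapply(seps, function(s) {
    pb <- fit_niche_posterior(sweep(xa, 2, c(s, 0), "+"),
                              n_draws = 400, seed = 4)
    pairwise_overlap(pa, pb, n_mc = 4000, seed = 5)
  })
  expect_true(all(diff(ovs) < 0))
  expect_true(all(ovs >= 0 & ovs <= 1))

  # determinism
  expect_identical(pairwise_overlap(pa, pfar, n_mc = 1000, seed = 9),
                   pairwise_overlap(pa, pfar, n_mc = 1000, seed = 9))
  expect_error(pairwise_overlap(pa, fit_niche_posterior(
    matrix(rnorm(30), 10, 3), n_draws = 10, seed = 1)), "dimensions")
})

test_that("plug-in overlap agrees with a 2-D quadrature oracle", {
  mean_a <- c(0, 0)
  cov_a <- matrix(c(1, 0.4, 0.4, 1.5), 2)
  mean_b <- c(1.2, -0.5)
  cov_b <- matrix(c(2, -0.3, -0.3, 0.8), 2)
  oracle <- quadrature_overlap_2d(mean_a, cov_a, mean_b, cov_b, alpha = 0.95)
  mc <- mvn_region_overlap(mean_a, cov_a, mean_b, cov_b, alpha = 0.95,
                           n_mc = 2e5, seed = 6)
  expect_equal(mc, oracle, tolerance = 0.01)
})

test_that("overlap matrices are seeded, order-invariant and row-summable", {
  set.seed(44)
  ps <- lapply(1:3, function(i)
    fit_niche_posterior(rmvn(40, c(3 * i, 0), diag(2)),
                        n_draws = 200, seed = i,
                        individual_id = sprintf("m%d", i)))
  names(ps) <- sprintf("m%d", 1:3)

  m1 <- overlap_matrix(ps, n_mc = 500, seed = 11)
  m2 <- overlap_matrix(ps, n_mc = 500, seed = 11)
  expect_identical(plain_matrix(m1), plain_matrix(m2)) # bit-identical reruns

  perm <- c("m3", "m1", "m2")
  m3 <- overlap_matrix(ps[perm], n_mc = 500, seed = 11)
  expect_identical(plain_matrix(m3), plain_matrix(m1)[perm, perm])

  expect_true(all(is.na(diag(m1))))
  expect_true(all(m1[!is.na(m1)] >= 0 & m1[!is.na(m1)] <= 1))

  two <- overlap_matrix(ps[1:2], n_mc = 200, seed = 1)
  expect_equal(sum(!is.na(two)), 2)

  # aggregate = row sums over the off-diagonal
  m <- matrix(c(NA, 0.1, 0.2, 0.3, NA, 0.4, 0.5, 0.6, NA), 3, 3,
              byrow = TRUE, dimnames = list(c("a", "b", "c"),
                                            c("a", "b", "c")))
  class(m) <- c("overlap_matrix", "matrix", "array")
  expect_equal(aggregate_ano(m)$ano, c(0.3, 0.7, 1.1))
})

test_that("the sample-level pipeline caps dimensions and separates clusters", {
  set.seed(45)
  tab <- simulate_population(sim_config(
    n_individuals = 3, calls_per_individual = 8,
    sigma_b = 400, sigma_w = 10, seed = 9))$table
  pcs <- call_pc_scores(tab)
  expect_message(
    suppressWarnings( # 8 calls against 7 dims: diffuse-posterior warning
      res <- acoustic_niche_overlap(pcs, n_mc = 400, n_draws = 150, seed = 2)),
    "capping niche dimensions at 7")
  expect_equal(res$dims, 7)
  # widely separated clusters barely overlap
  expect_true(all(res$ano$ano < 0.05))
})
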