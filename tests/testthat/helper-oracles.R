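# Small fixtures and independent oracles used across the suite.

# A tiny deterministic call table: `k` individuals x `n` calls built from
# shifted copies of a fixed contour plus a deterministic ripple (no RNG).
tiny_call_table <- function(k = 2, n = 3, shift = 50) {
  base <- seq(600, 1000, length.out = 10)
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(n)) {
      pfc <- base + (i - 1) * shift + 3 * j * (-1)^(seq_len(10) + j)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("m%02d", i), group_label = "G",
        call_id = sprintf("m%02d_c%02d", i, j),
        duration_s = 0.3 + 0.01 * i + 0.002 * j,
        t(setNames(pfc, sprintf("pfc_%02d", 1:10))))
    }
  }
  do.call(rbind, rows)
}

# Drop class/provenance so two call tables can be compared value-for-value.
plain_df <- function(t) {
  t <- as.data.frame(t)
  attr(t, "provenance") <- NULL
  rownames(t) <- NULL
  t
}

# Strip overlap_matrix attributes down to a plain numeric matrix.
plain_matrix <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

# Random orthogonal matrix via QR with sign fix.
random_orthogonal <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d)
}

# MVN sampler used by test fixtures.
rmvn <- function(n, mean, cov) {
  d <- length(mean)
  sweep(matrix(rnorm(n * d), n, d) %*% chol(cov), 2, mean, "+")
}

# Brute-force two-sided Wilcoxon rank-sum p-value: enumerate every
# assignment of the pooled sample to the two groups.
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pool), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Hand-rolled leave-one-out linear discriminant classifier: pooled
# within-class covariance, linear discriminant functions with priors.
loo_lda_percent <- function(x, labels, uniform_priors = FALSE) {
  x <- as.matrix(x)
  f <- factor(labels)
  correct <- 0L
  for (i in seq_len(nrow(x))) {
    xt <- x[-i, , drop = FALSE]
    ft <- droplevels(f[-i])
    lev <- levels(ft)
    mus <- t(sapply(lev, function(l) colMeans(xt[ft == l, , drop = FALSE])))
    ns <- table(ft)
    Sp <- Reduce(`+`, lapply(lev, function(l) {
      xi <- xt[ft == l, , drop = FALSE]
      crossprod(sweep(xi, 2, colMeans(xi), "-"))
    })) / (nrow(xt) - length(lev))
    Spi <- solve(Sp)
    pri <- if (uniform_priors) rep(1 / length(lev), length(lev)) else
      as.vector(ns) / nrow(xt)
    delta <- sapply(seq_along(lev), function(l) {
      m <- mus[l, ]
      drop(x[i, ] %*% Spi %*% m) - 0.5 * drop(m %*% Spi %*% m) + log(pri[l])
    })
    if (lev[which.max(delta)] == as.character(f[i])) correct <- correct + 1L
  }
  100 * correct / nrow(x)
}

# Grid-quadrature oracle for the 2-D plug-in niche overlap
# P(X_A inside the alpha ellipse of B): midpoint rule over a box covering
# the ellipse.
quadrature_overlap_2d <- function(mean_a, cov_a, mean_b, cov_b,
                                  alpha = 0.99, ngrid = 600) {
  q <- qchisq(alpha, df = 2)
  # bounding box of the ellipse of B
  half <- sqrt(q * diag(cov_b))
  xs <- seq(mean_b[1] - half[1], mean_b[1] + half[1], length.out = ngrid)
  ys <- seq(mean_b[2] - half[2], mean_b[2] + half[2], length.out = ngrid)
  dx <- diff(xs[1:2])
  dy <- diff(ys[1:2])
  g <- as.matrix(expand.grid(x = xs, y = ys))
  inside <- mahalanobis(g, mean_b, cov_b) <= q
  dens <- function(p) {
    ci <- solve(cov_a)
    dlt <- sweep(p, 2, mean_a, "-")
    exp(-0.5 * rowSums((dlt %*% ci) * dlt)) /
      (2 * pi * sqrt(det(cov_a)))
  }
  sum(dens(g[inside, , drop = FALSE])) * dx * dy
}
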