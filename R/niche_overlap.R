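# Batched matrix-vector product: A is d x d x K, y is K x d;
# returns z (K x d) with z[k, ] = A[, , k] %*% y[k, ]. Vectorized over K by
# looping over the d output coordinates only.
.batch_mat_vec <- function(A, y) {
  d <- dim(A)[1]
  K <- nrow(y)
  z <- matrix(0, K, d)
  ty <- t(y)
  for (i in seq_len(d)) {
    Ai <- matrix(A[i, , ], nrow = d, ncol = K)
    z[, i] <- colSums(Ai * ty)
  }
  z
}

#' Posterior draws for one individual's acoustic niche
#'
#' Models the individual's calls (rows of `x`, in score space) as draws
#' from a multivariate normal and samples the posterior of its mean and
#' covariance under the standard noninformative conjugate prior: the
#' covariance is drawn from an inverse-Wishart with `n - 1` degrees of
#' freedom and scale equal to the sample sum-of-squares matrix, and the
#' mean, given the covariance, is normal around the sample mean with
#' covariance `Sigma / n`. Draws are deterministic given `seed`.
#'
#' @param x Numeric matrix, calls x dimensions, of one individual's scores;
#'   needs `nrow(x) - 1 >= ncol(x)` for a proper posterior, and
#'   `nrow(x) >= ncol(x) + 2` is recommended (flagged otherwise).
#' @param n_draws Number of posterior draws (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param individual_id Optional identifier stored with the posterior.
#' @return Object of class `niche_posterior`: `mu` (draws x dims),
#'   `sigma` (dims x dims x draws), cached Cholesky factors for sampling
#'   and Mahalanobis evaluation, and bookkeeping fields.
#' @export
fit_niche_posterior <- function(x, n_draws = 1000, seed = NULL,
                                individual_id = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2L) stop("need >= 2 calls to fit a niche posterior")
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (n - 1L < d) {
    stop("need more calls than dimensions (n - 1 >= dims); ",
         "reduce the number of score dimensions")
  }
  low_n <- n < d + 2L
  if (low_n) {
    warning("fewer than dims + 2 calls; the posterior will be very diffuse")
  }
  xbar <- colMeans(x)
  S <- crossprod(sweep(x, 2, xbar, "-"))
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
    stop("singular sample covariance; reduce the number of score dimensions",
         call. = FALSE)
  })
  with_seed(seed, {
    W <- rWishart(n_draws, df = n - 1, Sigma = Sinv)
    mu <- matrix(0, n_draws, d)
    sigma <- array(0, c(d, d, n_draws))
    A <- array(0, c(d, d, n_draws)) # A %*% t(A) = Sigma (sampling root)
    V <- array(0, c(d, d, n_draws)) # t(V) %*% V = Sigma^-1 (precision chol)
    Id <- diag(d)
    z <- matrix(rnorm(n_draws * d), n_draws, d)
    for (k in seq_len(n_draws)) {
      Vk <- chol(W[, , k])          # W = Sigma^-1, so ||Vk y||^2 = Mahalanobis
      Ak <- backsolve(Vk, Id)       # Ak Ak' = W^-1 = Sigma
      V[, , k] <- Vk
      A[, , k] <- Ak
      sigma[, , k] <- tcrossprod(Ak)
      mu[k, ] <- xbar + (Ak %*% z[k, ]) / sqrt(n)
    }
    structure(list(individual_id = individual_id, mu = mu, sigma = sigma,
                   samp_chol = A, prec_chol = V, n_draws = n_draws,
                   dims = d, n_calls = n, xbar = xbar, low_n = low_n,
                   seed = seed),
              class = "niche_posterior")
  })
}

#' @export
print.niche_posterior <- function(x, ...) {
  cat(sprintf("niche_posterior%s: %d draws, %d dims, fit on %d calls\n",
              if (is.null(x$individual_id)) "" else
                paste0(" [", x$individual_id, "]"),
              x$n_draws, x$dims, x$n_calls))
  invisible(x)
}

#' Membership of a point in an alpha-level multivariate-normal niche region
#'
#' The alpha-level niche region of a multivariate normal is the ellipsoid
#' containing probability `alpha`; a point belongs iff its squared
#' Mahalanobis distance is at most the alpha quantile of the chi-square
#' distribution with `dims` degrees of freedom.
#'
#' @param x Numeric vector, or matrix with points in rows.
#' @param mean Mean vector of the normal.
#' @param covariance Positive-definite covariance matrix.
#' @param alpha Probability level of the region, in (0, 1).
#' @return Logical vector, one value per point.
#' @export
region_membership <- function(x, mean, covariance, alpha = 0.99) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- length(mean)
  if (ncol(x) != d || any(dim(covariance) != d)) {
    stop("dimension mismatch between x, mean and covariance")
  }
  stopifnot(alpha > 0, alpha < 1)
  mahalanobis(x, center = mean, cov = covariance) <= qchisq(alpha, df = d)
}

#' Directional pairwise acoustic-niche overlap
#'
#' Monte-Carlo estimate of the probability that a call produced by the
#' focal individual falls inside the `alpha`-level niche region of the
#' other individual, with the uncertainty of both individuals' niche
#' parameters integrated out: for each Monte-Carlo iteration a posterior
#' draw of the focal's (mean, covariance) generates a call, and a paired
#' posterior draw of the other's parameters defines the region. Posterior
#' draws are recycled when `n_mc` exceeds the number of stored draws. The
#' estimate is deterministic given `seed`.
#'
#' @param focal,other `niche_posterior` objects of equal dimension; the
#'   focal generates calls, the other defines the region.
#' @param alpha Niche-region probability level (default 0.99).
#' @param n_mc Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed or `NULL`.
#' @return Overlap probability in `[0, 1]`.
#' @export
pairwise_overlap <- function(focal, other, alpha = 0.99, n_mc = 10000,
                             seed = NULL) {
  stopifnot(inherits(focal, "niche_posterior"),
            inherits(other, "niche_posterior"))
  if (focal$dims != other$dims) {
    stop("focal and other posteriors have different dimensions")
  }
  stopifnot(alpha > 0, alpha < 1, n_mc >= 1)
  d <- focal$dims
  idx_f <- rep_len(seq_len(focal$n_draws), n_mc)
  idx_o <- rep_len(seq_len(other$n_draws), n_mc)
  with_seed(seed, {
    z <- matrix(rnorm(n_mc * d), n_mc, d)
    calls <- focal$mu[idx_f, , drop = FALSE] +
      .batch_mat_vec(focal$samp_chol[, , idx_f, drop = FALSE], z)
    y <- calls - other$mu[idx_o, , drop = FALSE]
    w <- .batch_mat_vec(other$prec_chol[, , idx_o, drop = FALSE], y)
    mean(rowSums(w^2) <= qchisq(alpha, df = d))
  })
}

#' Plug-in niche overlap between two known multivariate normals
#'
#' Monte-Carlo estimate of `P(X_A` inside the alpha-level region of `B)`
#' with both distributions' parameters treated as known (no posterior
#' uncertainty). Mainly useful for checking the Monte-Carlo machinery
#' against numeric integration.
#'
#' @param mean_a,cov_a Parameters of the generating normal.
#' @param mean_b,cov_b Parameters of the normal defining the region.
#' @param alpha Region probability level.
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Integer seed or `NULL`.
#' @return Overlap probability in `[0, 1]`.
#' @export
mvn_region_overlap <- function(mean_a, cov_a, mean_b, cov_b, alpha = 0.99,
                               n_mc = 10000, seed = NULL) {
  d <- length(mean_a)
  stopifnot(length(mean_b) == d, all(dim(cov_a) == d), all(dim(cov_b) == d))
  with_seed(seed, {
    z <- matrix(rnorm(n_mc * d), n_mc, d)
    x <- sweep(z %*% chol(cov_a), 2, mean_a, "+")
    mean(region_membership(x, mean_b, cov_b, alpha))
  })
}

#' All directional pairwise niche overlaps of a sample
#'
#' Fills every ordered pair (focal, other), focal generating the calls and
#' the other defining the region. Each pair uses a Monte-Carlo stream
#' derived deterministically from `seed` and the two individual ids, so the
#' matrix is reproducible and invariant to the order in which individuals
#' are supplied.
#'
#' @param posteriors Named list of `niche_posterior` objects (names = ids;
#'   unnamed lists use the posteriors' own `individual_id`).
#' @param alpha Niche-region probability level.
#' @param n_mc Monte-Carlo draws per pair.
#' @param seed Integer seed or `NULL`.
#' @return Matrix of class `overlap_matrix` (focal rows, other columns,
#'   `NA` diagonal) with attributes `alpha`, `n_mc`, `seed`, `dims`.
#' @export
overlap_matrix <- function(posteriors, alpha = 0.99, n_mc = 10000,
                           seed = NULL) {
  if (length(posteriors) < 2L) stop("need >= 2 individuals")
  ids <- names(posteriors) %||%
    vapply(posteriors, function(p) p$individual_id %||% NA_character_,
           character(1))
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("posteriors must carry unique individual ids")
  }
  n <- length(posteriors)
  m <- matrix(NA_real_, n, n, dimnames = list(focal = ids, other = ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- pairwise_overlap(posteriors[[i]], posteriors[[j]],
                                  alpha = alpha, n_mc = n_mc,
                                  seed = .id_seed(seed, ids[i], ids[j]))
    }
  }
  structure(m, alpha = alpha, n_mc = n_mc, seed = seed,
            dims = posteriors[[1]]$dims,
            class = c("overlap_matrix", "matrix", "array"))
}

#' Aggregate acoustic-niche overlap per individual
#'
#' For each focal individual, the SUM over all other individuals of the
#' probability that one of its calls falls inside the other's niche region
#' (the focal's row of the overlap matrix). Ranges from 0 (a fully
#' distinct caller) to `n - 1`.
#'
#' @param m An `overlap_matrix`.
#' @return Data frame: `individual_id`, `ano`.
#' @export
aggregate_ano <- function(m) {
  stopifnot(inherits(m, "overlap_matrix") || is.matrix(m))
  data.frame(individual_id = rownames(m),
             ano = rowSums(m, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Acoustic-niche-overlap pipeline for one sample of individuals
#'
#' Fits a niche posterior per individual on the first `dims` score
#' dimensions, computes all directional pairwise overlaps and aggregates
#' them per focal individual. The default dimensionality keeps every
#' component with non-negligible explained variance but is capped so that
#' each individual has more calls than dimensions (a multivariate normal
#' cannot be estimated otherwise); the cap, when active, is reported via
#' `message()` and recorded in the result.
#'
#' @param scores A `pc_scores` object or matrix.
#' @param labels Individual id per call (taken from `scores` if omitted).
#' @param alpha Niche-region probability level (default 0.99).
#' @param n_mc Monte-Carlo draws per ordered pair (default 10000).
#' @param n_draws Posterior draws per individual (default 1000).
#' @param dims Number of leading score dimensions to use; `NULL` (default)
#'   applies the capped rule above.
#' @param seed Integer seed; per-individual and per-pair streams are
#'   derived from it.
#' @return List of class `ano_result`: `overlap` (the matrix), `ano`
#'   (aggregate data frame), `dims`, `alpha`, `n_mc`, `n_draws`, `seed`.
#' @export
acoustic_niche_overlap <- function(scores, labels = NULL, alpha = 0.99,
                                   n_mc = 10000, n_draws = 1000,
                                   dims = NULL, seed = NULL) {
  rs <- .resolve_scores(scores, labels)
  counts <- table(rs$labels)
  min_calls <- min(counts)
  if (is.null(dims)) {
    ev <- if (inherits(scores, "pc_scores")) scores$explained_variance else
      apply(rs$x, 2, stats::var)
    dims <- sum(ev > 1e-8)
    cap <- min_calls - 1L
    if (dims > cap) {
      message("capping niche dimensions at ", cap,
              " (smallest individual has ", min_calls, " calls)")
      dims <- cap
    }
  }
  stopifnot(dims >= 1, dims <= ncol(rs$x))
  if (min_calls - 1L < dims) {
    stop("individual(s) with too few calls for ", dims, " dimensions")
  }
  x <- rs$x[, seq_len(dims), drop = FALSE]
  ids <- sort(unique(rs$labels))
  posteriors <- lapply(ids, function(id) {
    fit_niche_posterior(x[rs$labels == id, , drop = FALSE],
                        n_draws = n_draws,
                        seed = .id_seed(seed, "fit", id),
                        individual_id = id)
  })
  names(posteriors) <- ids
  m <- overlap_matrix(posteriors, alpha = alpha, n_mc = n_mc, seed = seed)
  structure(list(overlap = m, ano = aggregate_ano(m), dims = dims,
                 alpha = alpha, n_mc = n_mc, n_draws = n_draws,
                 seed = seed),
            class = "ano_result")
}

#' @export
print.ano_result <- function(x, ...) {
  cat(sprintf("acoustic niche overlap: %d individuals, %d dims, alpha = %g, n_mc = %d\n",
              nrow(x$overlap), x$dims, x$alpha, x$n_mc))
  print(x$ano)
  invisible(x)
}
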