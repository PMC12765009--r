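#' Extract the numeric feature matrix from a call table
#'
#' @param table A `call_table`.
#' @return Numeric matrix (calls x 11 features) with an attached `labels`
#'   attribute (data.frame: individual_id, group_label, call_id).
#' @export
feature_matrix <- function(table) {
  df <- as.data.frame(table)
  m <- as.matrix(df[.feature_cols])
  rownames(m) <- df$call_id
  attr(m, "labels") <- df[c("individual_id", "group_label", "call_id")]
  m
}

#' Center and scale feature columns
#'
#' Each column is transformed to mean 0 and sample standard deviation 1
#' (denominator n - 1). Constant columns are an error, named, since a
#' zero-variance feature cannot be scaled.
#'
#' @param m Numeric matrix or data frame (>= 2 rows).
#' @return Numeric matrix with `center` and `scale` attributes; any
#'   `labels` attribute on the input is carried over.
#' @export
standardize_features <- function(m) {
  labels <- attr(m, "labels")
  x <- as.matrix(m)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- which(sds == 0)
  if (length(zero)) {
    nm <- colnames(x)[zero] %||% as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, sds, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  attr(z, "labels") <- labels
  z
}

#' Principal-component scores of a standardized feature matrix
#'
#' Projects the rows on the eigenvectors of the sample covariance matrix,
#' components ordered by decreasing variance, all components retained and
#' scores NOT re-scaled — the per-component variances carry the information
#' that Beecher's statistic decomposes. The eigenvector sign is fixed
#' deterministically (the largest-magnitude loading element of each
#' component is positive) so score files are reproducible across platforms.
#' When there are no more rows than columns the trailing components have
#' (near-)zero variance; they are retained and their indices flagged.
#'
#' @param m Standardized numeric matrix (see [standardize_features()]).
#' @param labels Optional data.frame of per-row labels; defaults to the
#'   matrix's `labels` attribute.
#' @return An object of class `pc_scores`: list with `scores` (matrix),
#'   `loadings` (orthonormal columns), `explained_variance`, `labels`,
#'   `flagged` (indices of near-zero-variance components).
#' @export
pca_scores <- function(m, labels = NULL) {
  labels <- labels %||% attr(m, "labels")
  x <- as.matrix(m)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least 2 rows")
  x <- sweep(x, 2, colMeans(x), "-")
  # eigen-decomposition of the sample covariance keeps all components even
  # when there are fewer rows than features (trailing ones are flagged)
  eg <- eigen(cov(x), symmetric = TRUE)
  rot <- eg$vectors
  ev <- pmax(eg$values, 0)
  dimnames(rot) <- list(colnames(x), sprintf("PC%d", seq_len(ncol(x))))
  for (j in seq_len(ncol(rot))) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
  }
  sc <- x %*% rot
  flagged <- which(ev < 1e-10 * max(ev, 1))
  rownames(sc) <- rownames(x)
  structure(list(scores = sc, loadings = rot, explained_variance = ev,
                 labels = labels, flagged = flagged),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("pc_scores: %d calls x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained variance: ",
      paste(sprintf("%.3f", ev), collapse = " "), "\n")
  if (length(x$flagged)) {
    cat("near-zero-variance components:", paste(x$flagged, collapse = " "), "\n")
  }
  invisible(x)
}

#' Standardize and decorrelate a call table in one step
#'
#' Convenience wrapper: extract the 11 features, center and scale them, and
#' compute PCA scores carrying the call labels.
#'
#' @param table A `call_table`.
#' @return A `pc_scores` object.
#' @export
call_pc_scores <- function(table) {
  pca_scores(standardize_features(feature_matrix(table)))
}

#' Export PC scores as a flat delimited table
#'
#' @param pcs A `pc_scores` object.
#' @param path Output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
export_scores <- function(pcs, path) {
  stopifnot(inherits(pcs, "pc_scores"))
  sc <- pcs$scores
  colnames(sc) <- sprintf("pc_%02d", seq_len(ncol(sc)))
  df <- cbind(pcs$labels %||%
                data.frame(call_id = rownames(sc) %||%
                             as.character(seq_len(nrow(sc)))),
              as.data.frame(sc))
  .write_table_meta(df, path)
}

#' Basic two-component score plot
#'
#' Scatter of two principal components, coloured by individual — the usual
#' first look at whether calls cluster by caller.
#'
#' @param x A `pc_scores` object.
#' @param dims Length-2 integer vector of component indices.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pc_scores <- function(x, dims = c(1, 2), ...) {
  stopifnot(length(dims) == 2L, all(dims <= ncol(x$scores)))
  ind <- x$labels$individual_id %||% rep("?", nrow(x$scores))
  f <- factor(ind)
  cols <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")
  graphics::plot(x$scores[, dims[1]], x$scores[, dims[2]],
                 col = cols[as.integer(f)], pch = 19,
                 xlab = sprintf("PC%d", dims[1]),
                 ylab = sprintf("PC%d", dims[2]), ...)
  invisible(x)
}
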