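# Resolve (scores, labels) arguments: accept a pc_scores object (labels
# carried inside) or a plain matrix plus an explicit label vector.
.resolve_scores <- function(scores, labels = NULL, group = FALSE) {
  if (inherits(scores, "pc_scores")) {
    x <- scores$scores
    lab <- labels %||% scores$labels$individual_id
    grp <- if (!is.null(scores$labels)) scores$labels$group_label else NULL
  } else {
    x <- as.matrix(scores)
    lab <- labels %||% attr(scores, "labels")$individual_id
    grp <- attr(scores, "labels")$group_label
  }
  if (is.null(lab)) stop("individual labels are required")
  lab <- as.character(lab)
  if (length(lab) != nrow(x)) {
    stop("labels length (", length(lab), ") != number of rows (", nrow(x), ")")
  }
  list(x = x, labels = lab, group = grp)
}

#' One-way sums-of-squares decomposition for one variable
#'
#' Decomposes the total sum of squares of `values` around the grand mean
#' into a within-individual part (squared deviations from each individual's
#' own mean) and an among-individual remainder, with the fixed-effects
#' one-way F statistic (`df_among = k - 1`, `df_within = N - k`) and its
#' p-value. This decomposition is the building block of Beecher's
#' statistic.
#'
#' @param values Numeric vector, one value per call.
#' @param labels Individual id per call; every individual needs >= 2 calls.
#' @return List: `ss_total`, `ss_within`, `ss_among`, `df_among`,
#'   `df_within`, `f`, `p`, `degenerate` (TRUE when `ss_total` is 0, in
#'   which case `f`/`p` are `NA`).
#' @examples
#' anova_decomposition(c(0, 2, 4, 6), c("a", "a", "b", "b"))
#' @export
anova_decomposition <- function(values, labels) {
  values <- as.numeric(values)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop("need >= 2 individuals")
  if (any(counts < 2L)) {
    stop("individual(s) with < 2 calls: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  n <- length(values)
  k <- length(counts)
  ss_total <- sum((values - mean(values))^2)
  gm <- tapply(values, labels, mean)
  ss_within <- sum((values - gm[labels])^2)
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- n - k
  if (ss_total == 0) {
    return(list(ss_total = 0, ss_within = 0, ss_among = 0,
                df_among = df_among, df_within = df_within,
                f = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  f <- (ss_among / df_among) / (ss_within / df_within)
  p <- pf(f, df_among, df_within, lower.tail = FALSE)
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = df_among, df_within = df_within, f = f, p = p,
       degenerate = FALSE)
}

#' Beecher's information statistic (HS)
#'
#' Per principal component `c`, the identity information is
#' `HS_c = 0.5 * log2(SS_total / SS_within)` — the ratio of the component's
#' total variation to its within-individual variation, on a log scale in
#' bits. Components are uncorrelated, so per-component values sum to the
#' statistic of the whole call. Two totals are always reported:
#' `hs_all` (sum over every component) and `hs_significant` (sum over
#' components whose one-way ANOVA shows a significant individual effect,
#' p < `p_threshold`); `variant` selects which of the two feeds the
#' signature capacity `n_signatures = floor(2^HS)`. An alternative
#' estimator using degrees-of-freedom-corrected mean squares instead of raw
#' sums of squares is available via `estimator = "ms_ratio"`.
#'
#' @param scores A `pc_scores` object, or a matrix of uncorrelated
#'   variables (calls x components).
#' @param labels Individual id per call (taken from `scores` if omitted).
#' @param variant Which total the headline value and `n_signatures` use:
#'   `"significant_only"` (default) or `"all"`.
#' @param estimator `"ss_ratio"` (default; raw sums of squares) or
#'   `"ms_ratio"` (mean squares, `SS/(N-1)` over `SS/(N-k)`).
#' @param p_threshold Significance threshold for the per-component ANOVA.
#' @return Object of class `hs_result`: `per_component_hs`,
#'   `per_component_p`, `hs_all`, `hs_significant`, `hs_selected`,
#'   `n_signatures`, plus the options used.
#' @export
calc_hs <- function(scores, labels = NULL,
                    variant = c("significant_only", "all"),
                    estimator = c("ss_ratio", "ms_ratio"),
                    p_threshold = 0.05) {
  variant <- match.arg(variant)
  estimator <- match.arg(estimator)
  rs <- .resolve_scores(scores, labels)
  x <- rs$x
  lab <- rs$labels
  counts <- table(lab)
  keep <- lab %in% names(counts)[counts >= 2]
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " call(s) of individual(s) with < 2 calls")
    x <- x[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  nc <- ncol(x)
  hs <- p <- numeric(nc)
  for (j in seq_len(nc)) {
    a <- anova_decomposition(x[, j], lab)
    if (a$degenerate) {
      hs[j] <- 0
      p[j] <- NA_real_
      next
    }
    if (a$ss_within == 0) {
      stop("component ", j, " has zero within-individual variation ",
           "(duplicated calls?); HS would be infinite")
    }
    ratio <- if (estimator == "ss_ratio") {
      a$ss_total / a$ss_within
    } else {
      (a$ss_total / (a$df_among + a$df_within)) / (a$ss_within / a$df_within)
    }
    hs[j] <- 0.5 * log2(ratio)
    p[j] <- a$p
  }
  sig <- !is.na(p) & p < p_threshold
  hs_all <- sum(hs)
  hs_significant <- sum(hs[sig])
  hs_selected <- if (variant == "all") hs_all else hs_significant
  structure(list(per_component_hs = hs, per_component_p = p,
                 hs_all = hs_all, hs_significant = hs_significant,
                 hs_selected = hs_selected,
                 n_signatures = signatures_from_hs(hs_selected),
                 variant = variant, estimator = estimator,
                 p_threshold = p_threshold,
                 n_individuals = length(unique(lab)),
                 n_calls = length(lab)),
            class = "hs_result")
}

#' @export
print.hs_result <- function(x, ...) {
  cat(sprintf(paste0("Beecher's statistic: HS = %.2f bits (%s, %s), ",
                     "%d unique signatures\n"),
              x$hs_selected, x$variant, x$estimator, x$n_signatures))
  cat(sprintf("  hs_all = %.2f, hs_significant = %.2f (%d of %d components, p < %g)\n",
              x$hs_all, x$hs_significant,
              sum(!is.na(x$per_component_p) & x$per_component_p < x$p_threshold),
              length(x$per_component_hs), x$p_threshold))
  invisible(x)
}

#' Signature capacity implied by an HS value
#'
#' `floor(2^hs)` — the number of individuals whose identities `hs` bits of
#' information can keep apart.
#'
#' @param hs Non-negative HS value in bits.
#' @return Integer signature count (>= 1).
#' @examples
#' signatures_from_hs(6.38) # 83
#' @export
signatures_from_hs <- function(hs) {
  if (!is.numeric(hs) || length(hs) != 1L || is.na(hs) || hs < 0) {
    stop("hs must be a single non-negative number")
  }
  as.integer(floor(2^hs))
}

#' Discrimination score by leave-one-out linear discriminant analysis
#'
#' Classifies every call with a linear discriminant (shared pooled
#' within-class covariance, class-mean discriminants) fitted on all the
#' other calls, and reports the percentage assigned to the correct
#' individual, along with the chance level `100/n` and the index of vocal
#' stereotypy `IVS = DS / chance`. Classification is delegated to
#' [MASS::lda()] with leave-one-out cross-validation.
#'
#' @param scores A `pc_scores` object or matrix (calls x components).
#' @param labels Individual id per call (taken from `scores` if omitted).
#' @param priors `"proportional"` (to class call counts; default) or
#'   `"uniform"`.
#' @param n_components Use only the first `n_components` score columns;
#'   the documented fallback when the pooled covariance is singular.
#' @return Object of class `ds_result`: `ds_percent`, `n_individuals`,
#'   `chance_percent`, `ivs`, `confusion` (true x predicted counts).
#' @export
calc_ds <- function(scores, labels = NULL,
                    priors = c("proportional", "uniform"),
                    n_components = NULL) {
  priors <- match.arg(priors)
  rs <- .resolve_scores(scores, labels)
  x <- rs$x
  lab <- rs$labels
  counts <- table(lab)
  if (length(counts) < 2L) stop("need >= 2 individuals")
  keep <- lab %in% names(counts)[counts >= 2]
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " call(s) of individual(s) with < 2 calls")
    x <- x[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  if (!is.null(n_components)) {
    stopifnot(n_components >= 1, n_components <= ncol(x))
    x <- x[, seq_len(n_components), drop = FALSE]
  }
  f <- factor(lab)
  k <- nlevels(f)
  prior <- if (priors == "uniform") rep(1 / k, k) else
    as.vector(table(f)) / length(f)
  fit <- tryCatch(
    MASS::lda(x, grouping = f, prior = prior, CV = TRUE),
    error = function(e) {
      stop("linear discriminant failed (", conditionMessage(e),
           "); the pooled within-class covariance may be singular - ",
           "try a smaller n_components", call. = FALSE)
    })
  pred <- fit$class
  ds <- 100 * mean(pred == f)
  structure(list(ds_percent = ds, n_individuals = k,
                 chance_percent = 100 / k,
                 ivs = calc_ivs(ds, k),
                 confusion = table(true = f, predicted = pred),
                 priors = priors,
                 n_components = n_components %||% ncol(x)),
            class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat(sprintf("Discrimination score: DS = %.1f%% (%d individuals, chance %.1f%%), IVS = %.2f\n",
              x$ds_percent, x$n_individuals, x$chance_percent, x$ivs))
  invisible(x)
}

#' Index of vocal stereotypy
#'
#' `IVS = DS / chance assignment`, with chance assignment `100/n`
#' individuals; i.e. `ds_percent * n_individuals / 100`, reported to two
#' decimals. A chance-corrected discrimination score that can be compared
#' across studies with similar numbers of individuals.
#'
#' @param ds_percent Discrimination score in percent (0-100).
#' @param n_individuals Number of individuals (>= 2).
#' @return IVS ratio, rounded to 2 decimals.
#' @examples
#' calc_ivs(87.7, 22) # 19.29
#' @export
calc_ivs <- function(ds_percent, n_individuals) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 2) {
    stop("n_individuals must be >= 2")
  }
  if (!is.numeric(ds_percent) || length(ds_percent) != 1L ||
      ds_percent < 0 || ds_percent > 100) {
    stop("ds_percent must be in [0, 100]")
  }
  round(ds_percent * n_individuals / 100, 2)
}

#' Within-individual acoustic distance (WID)
#'
#' For each individual: the mean Euclidean distance of its calls to its own
#' centroid (score-space mean of its calls). Low WID means the individual
#' calls consistently. Individuals with fewer than 2 calls are skipped with
#' a warning.
#'
#' @param scores A `pc_scores` object or matrix.
#' @param labels Individual id per call (taken from `scores` if omitted).
#' @return Data frame: `individual_id`, `n_calls`, `wid`.
#' @export
calc_wid <- function(scores, labels = NULL) {
  rs <- .resolve_scores(scores, labels)
  counts <- table(rs$labels)
  skip <- names(counts)[counts < 2]
  if (length(skip)) {
    warning("skipping individual(s) with < 2 calls: ",
            paste(skip, collapse = ", "))
  }
  ids <- setdiff(names(counts), skip)
  wid <- vapply(ids, function(id) {
    xi <- rs$x[rs$labels == id, , drop = FALSE]
    ctr <- colMeans(xi)
    mean(sqrt(rowSums(sweep(xi, 2, ctr, "-")^2)))
  }, numeric(1))
  data.frame(individual_id = ids,
             n_calls = as.vector(counts[ids]),
             wid = as.vector(wid), stringsAsFactors = FALSE)
}

#' Between-individual acoustic distance (BID)
#'
#' The Euclidean distance from the population centroid — the score-space
#' mean over ALL calls of the sample, not the mean of individual centroids
#' — to each individual's centroid. Large BID means the individual sits far
#' out in the shared acoustic space.
#'
#' @param scores A `pc_scores` object or matrix.
#' @param labels Individual id per call (taken from `scores` if omitted).
#' @return Data frame: `individual_id`, `bid`.
#' @export
calc_bid <- function(scores, labels = NULL) {
  rs <- .resolve_scores(scores, labels)
  pop <- colMeans(rs$x)
  ids <- sort(unique(rs$labels))
  bid <- vapply(ids, function(id) {
    ctr <- colMeans(rs$x[rs$labels == id, , drop = FALSE])
    sqrt(sum((ctr - pop)^2))
  }, numeric(1))
  data.frame(individual_id = ids, bid = as.vector(bid),
             stringsAsFactors = FALSE)
}
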