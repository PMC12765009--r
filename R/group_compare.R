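#' Wilcoxon rank-sum test between two samples
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test via
#' [stats::wilcox.test()] with its default behaviour: the statistic W is
#' the rank sum of the first sample minus `n1 (n1 + 1) / 2` (mid-ranks for
#' ties); the p-value is exact when both samples have fewer than 50
#' observations and there are no ties, and otherwise uses the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class `rank_sum`: `w`, `p`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ht <- suppressWarnings(wilcox.test(x, y))
  exact <- length(x) < 50 && length(y) < 50 && !anyDuplicated(c(x, y))
  structure(list(w = unname(ht$statistic), p = ht$p.value,
                 method = if (exact) "exact" else "normal_approx",
                 n1 = length(x), n2 = length(y)),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum: W = %g, p = %.4g (%s; n1 = %d, n2 = %d)\n",
              x$w, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

#' Median and interquartile range of a sample
#'
#' Quartiles use linear interpolation of the order statistics at position
#' `h = (n - 1) p + 1` (quantile type 7, the R default).
#'
#' @param x Non-empty numeric sample.
#' @param group_label Optional label carried into the summary.
#' @return List of class `group_summary`: `group_label`, `n`, `median`,
#'   `q1`, `q3`, `iqr`.
#' @export
median_iqr <- function(x, group_label = NA_character_) {
  x <- as.numeric(x)
  if (!length(x)) stop("sample must be non-empty")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(list(group_label = group_label, n = length(x),
                 median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1]),
            class = "group_summary")
}

#' Compare a per-individual metric between two conditions
#'
#' Runs a two-sided Wilcoxon rank-sum test between the two groups'
#' per-individual values and summarises each group by median and IQR; one
#' raw p-value per metric, no multiplicity adjustment.
#'
#' @param values Numeric vector, one value per individual.
#' @param groups Group label per individual; exactly two labels must be
#'   present.
#' @param alpha Significance threshold (default 0.05).
#' @param metric Optional metric name carried into the result.
#' @return List of class `condition_comparison`: `metric`, `test`
#'   (`rank_sum`), `summaries` (list of two `group_summary`),
#'   `significant`, `alpha`.
#' @export
compare_conditions <- function(values, groups, alpha = 0.05, metric = NULL) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  labs <- unique(groups)
  if (length(labs) != 2L) {
    stop("exactly two group labels required, got: ",
         paste(labs, collapse = ", "))
  }
  xs <- split(values, factor(groups, levels = labs))
  if (any(lengths(xs) < 2L)) {
    warning("group(s) with < 2 individuals: ",
            paste(labs[lengths(xs) < 2], collapse = ", "))
  }
  test <- wilcoxon_rank_sum(xs[[1]], xs[[2]])
  structure(list(metric = metric,
                 groups = labs,
                 test = test,
                 summaries = lapply(labs, function(g)
                   median_iqr(xs[[g]], group_label = g)),
                 significant = test$p < alpha,
                 alpha = alpha),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("%s: W = %g, p = %.4g%s\n",
              x$metric %||% "comparison", x$test$w, x$test$p,
              if (x$significant) " *" else ""))
  for (s in x$summaries) {
    cat(sprintf("  %s: n = %d, median = %.4g, IQR = %.4g\n",
                s$group_label, s$n, s$median, s$iqr))
  }
  invisible(x)
}

#' Tidy one-row summary of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @return One-row data frame mirroring the usual results-sentence
#'   structure (metric, W, p, per-group median and IQR, n).
#' @export
comparison_row <- function(x) {
  stopifnot(inherits(x, "condition_comparison"))
  s1 <- x$summaries[[1]]
  s2 <- x$summaries[[2]]
  data.frame(metric = x$metric %||% NA_character_,
             group1 = s1$group_label, group2 = s2$group_label,
             w = x$test$w, p = x$test$p, method = x$test$method,
             significant = x$significant,
             n1 = s1$n, median1 = s1$median, iqr1 = s1$iqr,
             n2 = s2$n, median2 = s2$median, iqr2 = s2$iqr,
             stringsAsFactors = FALSE)
}
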