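# Default rise-fall 'hoook' base contour, spanning roughly the 630-1000 Hz
# band observed for the little owl's territorial-call fundamental.
.default_base_contour <- c(632, 700, 790, 880, 955, 1003, 985, 920, 840, 700)

#' Configuration for the hierarchical call simulator
#'
#' The simulator emulates the hierarchical statistical structure the
#' individuality analysis assumes: every individual has a stable mean call
#' (a between-individual Gaussian offset around a shared base contour) and
#' every call adds independent within-individual Gaussian noise. The
#' identity signal strength is set by the ratio `sigma_b / sigma_w`.
#'
#' `sigma_b` and `sigma_w` may be 11-vectors (per-feature standard
#' deviations: Hz for the 10 contour points, seconds for duration) or
#' scalars, in which case the scalar is the contour standard deviation in
#' Hz and the duration standard deviation is scaled proportionally
#' (`scalar * base_duration_s / mean(base_contour_hz)`), keeping the
#' relative variability of duration comparable to that of frequency.
#'
#' @param n_individuals Number of individuals (>= 2; default 22, a typical
#'   sample for one density condition).
#' @param calls_per_individual Calls per individual (>= 2; scalar or
#'   per-individual vector; default 25).
#' @param base_contour_hz Shared base contour, 10 frequencies in Hz
#'   (default a rise-fall shape spanning about 630-1000 Hz).
#' @param base_duration_s Shared base call duration in seconds
#'   (default 0.35).
#' @param sigma_b Between-individual standard deviation per feature
#'   (default 60 Hz / 0.04 s — about 1.7 times `sigma_w`, a clearly
#'   individualised signal).
#' @param sigma_w Within-individual standard deviation per feature
#'   (default 35 Hz / 0.025 s).
#' @param contour_smoothness Number of smooth cosine basis functions used
#'   to shape each individual's contour offset; 0 (default) draws
#'   independent offsets per feature. Smooth offsets correlate neighbouring
#'   contour points, as pitch contours of real calls do.
#' @param seed Integer seed (default 1).
#' @param group_label Group label written into the table (default
#'   `"GROUP"`).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 22, calls_per_individual = 25,
                       base_contour_hz = .default_base_contour,
                       base_duration_s = 0.35,
                       sigma_b = 60, sigma_w = 35,
                       contour_smoothness = 0, seed = 1,
                       group_label = "GROUP") {
  stopifnot(n_individuals >= 2, all(calls_per_individual >= 2),
            length(base_contour_hz) == 10, all(base_contour_hz > 0),
            base_duration_s > 0, contour_smoothness >= 0)
  expand_sigma <- function(s, what) {
    s <- as.numeric(s)
    if (length(s) == 1L) {
      s <- c(rep(s, 10), s * base_duration_s / mean(base_contour_hz))
    }
    if (length(s) != 11L) stop(what, " must be a scalar or an 11-vector")
    s
  }
  sigma_b <- expand_sigma(sigma_b, "sigma_b")
  sigma_w <- expand_sigma(sigma_w, "sigma_w")
  if (any(sigma_b < 0)) stop("sigma_b must be >= 0")
  if (any(sigma_w <= 0)) stop("sigma_w must be > 0")
  calls <- if (length(calls_per_individual) == 1L) {
    rep(as.integer(calls_per_individual), n_individuals)
  } else {
    if (length(calls_per_individual) != n_individuals) {
      stop("calls_per_individual must be scalar or length n_individuals")
    }
    as.integer(calls_per_individual)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 calls_per_individual = calls,
                 base_contour_hz = as.numeric(base_contour_hz),
                 base_duration_s = base_duration_s,
                 sigma_b = sigma_b, sigma_w = sigma_w,
                 contour_smoothness = as.integer(contour_smoothness),
                 seed = as.integer(seed),
                 group_label = as.character(group_label)),
            class = "sim_config")
}

#' Simulate a call population with known ground truth
#'
#' Individual mean vectors are `base + b_i` with Gaussian offsets `b_i`
#' (independent per feature, or combined from `contour_smoothness` cosine
#' basis functions and rescaled so every contour feature keeps marginal
#' standard deviation `sigma_b`); calls are `m_i + e_ij` with independent
#' Gaussian within-individual noise of standard deviation `sigma_w` per
#' feature. Durations are floored at 0.05 s. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `simulated_dataset`: `table` (a `call_table`) and
#'   `truth` (per-individual mean matrix, `sigma_b`, `sigma_w`, `seed`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$n_individuals
  base <- c(cfg$base_contour_hz, cfg$base_duration_s)
  with_seed(cfg$seed, {
    if (cfg$contour_smoothness == 0L) {
      b <- sweep(matrix(rnorm(k * 11), k, 11), 2, cfg$sigma_b, "*")
    } else {
      s <- cfg$contour_smoothness
      # cosine basis over the 10 contour positions; rows rescaled so each
      # feature's marginal sd is exactly sigma_b
      t10 <- (seq_len(10) - 0.5) / 10
      B <- vapply(seq_len(s), function(j) cos(pi * (j - 1) * t10),
                  numeric(10))
      rown <- sqrt(rowSums(B^2))
      coef <- matrix(rnorm(k * s), k, s)
      pfc_off <- (coef %*% t(B / rown)) *
        matrix(cfg$sigma_b[1:10], k, 10, byrow = TRUE)
      dur_off <- rnorm(k, 0, cfg$sigma_b[11])
      b <- cbind(pfc_off, dur_off)
    }
    means <- sweep(b, 2, base, "+")
    ids <- sprintf("%s_m%02d", cfg$group_label, seq_len(k))
    rownames(means) <- ids
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      n_i <- cfg$calls_per_individual[i]
      e <- sweep(matrix(rnorm(n_i * 11), n_i, 11), 2, cfg$sigma_w, "*")
      x <- sweep(e, 2, means[i, ], "+")
      x[, 11] <- pmax(x[, 11], 0.05)
      df <- as.data.frame(x)
      names(df) <- .feature_cols
      rows[[i]] <- cbind(
        data.frame(individual_id = ids[i],
                   group_label = cfg$group_label,
                   call_id = sprintf("%s_c%02d", ids[i], seq_len(n_i)),
                   stringsAsFactors = FALSE),
        df[.pfc_cols], duration_s = df$duration_s)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[c("individual_id", "group_label", "call_id", "duration_s",
                 .pfc_cols)]
    table <- as_call_table(tab, provenance = c(
      "source: simulate_population",
      paste0("seed: ", cfg$seed),
      paste0("group_label: ", cfg$group_label)))
    structure(list(table = table,
                   truth = list(means = means, sigma_b = cfg$sigma_b,
                                sigma_w = cfg$sigma_w, seed = cfg$seed)),
              class = "simulated_dataset")
  })
}

#' Large-sample HS implied by a simulator configuration
#'
#' Under the independent-feature simulation model, each feature's
#' total-to-within variance ratio tends to `1 + sigma_b^2 / sigma_w^2` as
#' the numbers of individuals and calls grow, so Beecher's statistic tends
#' to the sum over features of `0.5 * log2(1 + sigma_b^2 / sigma_w^2)`.
#' This is the large-sample limit, not a finite-sample expectation: with
#' `n` calls per individual the among-individual mean square also carries
#' within-noise of order `sigma_w^2 / n`, so finite samples overshoot the
#' limit slightly.
#'
#' @param cfg A [sim_config()] with `contour_smoothness = 0`.
#' @return HS limit in bits.
#' @examples
#' expected_hs(sim_config(sigma_b = rep(sqrt(3), 11), sigma_w = rep(1, 11)))
#' @export
expected_hs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$contour_smoothness != 0L) {
    stop("expected_hs() requires the independent-feature model ",
         "(contour_smoothness = 0)")
  }
  sum(0.5 * log2(1 + (cfg$sigma_b / cfg$sigma_w)^2))
}

#' Simulate a two-condition individuality study
#'
#' Generates a pair of call populations ready for the full pipeline. The
#' defaults mirror the between-population design of the motivating study
#' — two conditions of 22 individuals with about 25 calls each; pass
#' configurations with 14 and 10 individuals for the within-population
#' (clumped/isolated) design.
#'
#' @param cfg_dense,cfg_sparse [sim_config()]s for the dense and sparse
#'   condition; their `group_label`s must differ.
#' @return List of class `two_condition_study` with elements `dense` and
#'   `sparse` (each a `simulated_dataset`).
#' @export
simulate_two_condition_study <- function(
    cfg_dense = sim_config(group_label = "HIGH", seed = 101),
    cfg_sparse = sim_config(group_label = "LOW", seed = 102)) {
  stopifnot(inherits(cfg_dense, "sim_config"),
            inherits(cfg_sparse, "sim_config"))
  if (cfg_dense$group_label == cfg_sparse$group_label) {
    stop("the two conditions need distinct group labels")
  }
  structure(list(dense = simulate_population(cfg_dense),
                 sparse = simulate_population(cfg_sparse)),
            class = "two_condition_study")
}
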