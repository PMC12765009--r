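`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the global
#' random-number stream. A `NULL` seed evaluates `code` unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a base seed and one or more string ids.
# Keeps per-pair / per-individual Monte Carlo streams independent of the
# order in which individuals are processed. Always < 2^31.
.id_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (s in c(...)) {
    v <- utf8ToInt(as.character(s))
    h <- (h * 31 + sum(v * seq_along(v))) %% 1000003
  }
  as.integer((as.integer(seed) %% 1000003) * 1009 + h)
}

# Columns holding the 10 resampled peak-frequency-contour values.
.pfc_cols <- sprintf("pfc_%02d", 1:10)
.feature_cols <- c(.pfc_cols, "duration_s")

# Write a data.frame as TSV with '#'-prefixed metadata header lines.
.write_table_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = " "),
                              character(1))), con)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
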