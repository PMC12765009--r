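#' Assemble a call table from a data frame
#'
#' A call table is the package's atomic data structure: one row per call
#' with columns `individual_id`, `group_label`, `call_id`, `duration_s` and
#' the ten resampled peak-frequency-contour values `pfc_01`..`pfc_10` (Hz).
#' The constructor validates types, positivity/finiteness and uniqueness of
#' `(individual_id, call_id)` pairs. Individuals with fewer than 2 calls are
#' retained (a warning is raised and noted in the provenance) but are
#' excluded from metric computations downstream, where within-individual
#' variation would be undefined.
#'
#' @param df Data frame with the required columns.
#' @param provenance Character vector of free-text provenance notes
#'   (source file, dialect, simulation seed, ...).
#' @return A `call_table` (a data.frame subclass with a `provenance`
#'   attribute).
#' @export
as_call_table <- function(df, provenance = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("individual_id", "group_label", "call_id", .feature_cols)
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("call table must be non-empty")
  df <- df[req]
  df$individual_id <- as.character(df$individual_id)
  df$group_label <- as.character(df$group_label)
  df$call_id <- as.character(df$call_id)

  dur <- suppressWarnings(as.numeric(df$duration_s))
  bad <- which(!is.finite(dur) | dur <= 0)
  if (length(bad)) {
    stop("invalid duration_s (non-numeric or not > 0) in row(s): ",
         paste(bad, collapse = ", "))
  }
  df$duration_s <- dur
  for (col in .pfc_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-finite ", col, " in row(s): ", paste(bad, collapse = ", "))
    }
    df[[col]] <- v
  }
  key <- paste(df$individual_id, df$call_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, call_id) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  counts <- table(df$individual_id)
  few <- names(counts)[counts < 2]
  if (length(few)) {
    note <- paste0("individual(s) with < 2 calls (excluded from metrics): ",
                   paste(few, collapse = ", "))
    warning(note)
    provenance <- c(provenance, note)
  }
  structure(df, provenance = provenance,
            class = c("call_table", "data.frame"))
}

#' @export
print.call_table <- function(x, ...) {
  cat(sprintf("call_table: %d calls, %d individuals, group(s): %s\n",
              nrow(x), length(unique(x$individual_id)),
              paste(unique(x$group_label), collapse = ", ")))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("provenance:", paste(prov, collapse = "; "), "\n")
  NextMethod()
}

#' Read a call-feature table
#'
#' Two dialects are supported. `"flat"` is the package's own delimited
#' format (tab or comma separated, sniffed from the header line) with exact
#' column names `individual_id`, `group_label`, `call_id`, `duration_s`,
#' `pfc_01`..`pfc_10`. `"raven"` is a tab-delimited selection table in the
#' shape exported by Raven-style measurement software: begin/end time
#' columns, an annotation column per selection naming the individual
#' (and optionally the group), and two or more contour columns whose names
#' share a configurable prefix — one peak-frequency value per spectrogram
#' slice, with trailing slices of shorter calls left empty. Raven rows are
#' converted to exactly 10 contour values via [resample_evenly()]; duration
#' is `end - begin`.
#'
#' @param path Path of the file to read.
#' @param dialect `"flat"` or `"raven"`.
#' @param contour_prefix Raven dialect: common prefix of the contour columns.
#' @param begin_col,end_col Raven dialect: names of the begin/end time
#'   columns (seconds).
#' @param individual_col,group_col Raven dialect: annotation columns naming
#'   the individual and the group; if `group_col` is absent from the file
#'   the group label `"ALL"` is used.
#' @param call_id_col Raven dialect: column providing the call id; defaults
#'   to the `Selection` column when present, otherwise the row number.
#' @return A `call_table`; row order of the file is preserved.
#' @export
read_call_table <- function(path, dialect = c("flat", "raven"),
                            contour_prefix = "Peak Freq Contour",
                            begin_col = "Begin Time (s)",
                            end_col = "End Time (s)",
                            individual_col = "Individual",
                            group_col = "Group",
                            call_id_col = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "flat") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#",
                     colClasses = "character")
    return(as_call_table(df, provenance = c(
      paste0("source: ", path), "dialect: flat")))
  }

  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "\"")
  for (col in c(begin_col, end_col, individual_col)) {
    if (!col %in% names(df)) {
      stop("missing required column: ", col)
    }
  }
  ccols <- names(df)[startsWith(names(df), contour_prefix)]
  if (length(ccols) < 2L) {
    stop("need >= 2 contour columns with prefix \"", contour_prefix, "\"")
  }
  grp <- if (group_col %in% names(df)) as.character(df[[group_col]]) else
    rep("ALL", nrow(df))
  cid <- if (!is.null(call_id_col)) {
    if (!call_id_col %in% names(df)) stop("missing required column: ", call_id_col)
    as.character(df[[call_id_col]])
  } else if ("Selection" %in% names(df)) {
    as.character(df$Selection)
  } else {
    sprintf("sel%03d", seq_len(nrow(df)))
  }

  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    b <- suppressWarnings(as.numeric(df[[begin_col]][i]))
    e <- suppressWarnings(as.numeric(df[[end_col]][i]))
    if (!is.finite(b) || !is.finite(e) || e <= b) {
      stop("invalid begin/end time in row ", i)
    }
    vals <- suppressWarnings(as.numeric(unlist(df[i, ccols])))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) {
      stop("fewer than 2 contour samples in row ", i)
    }
    pfc <- resample_evenly(raw_contour(cid[i], b, e, vals), 10)
    row <- c(list(individual_id = as.character(df[[individual_col]][i]),
                  group_label = grp[i], call_id = cid[i],
                  duration_s = e - b),
             as.list(stats::setNames(pfc, .pfc_cols)))
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  as_call_table(out, provenance = c(
    paste0("source: ", path), "dialect: raven",
    paste0("contour_prefix: ", contour_prefix)))
}

#' Write a call table in the flat dialect
#'
#' Writes tab-separated text with full numeric precision (`%.17g`), so that
#' `read_call_table()` reproduces the table exactly.
#'
#' @param table A `call_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_call_table <- function(table, path) {
  if (!inherits(table, "call_table")) {
    stop("write_call_table() expects a call_table")
  }
  if (nrow(table) == 0L) stop("refusing to write an empty call table")
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a call table against plausibility rules
#'
#' Reports (without modifying the table) per-record violations — peak
#' frequencies outside the plausible band, non-finite values, duplicate call
#' ids — and per-individual call counts, flagging individuals with fewer
#' than 2 calls. The default band is the 500-2000 Hz range of the little
#' owl's territorial-call fundamental.
#'
#' @param table A `call_table` (or data frame with the same columns).
#' @param freq_band_hz Length-2 numeric `(low, high)` plausible band in Hz.
#' @return A list of class `call_validation` with elements `violations`
#'   (data.frame: row, individual_id, call_id, type, detail) and
#'   `call_counts` (data.frame: individual_id, n_calls).
#' @export
validate_call_table <- function(table, freq_band_hz = c(500, 2000)) {
  stopifnot(length(freq_band_hz) == 2L, freq_band_hz[1] < freq_band_hz[2])
  df <- as.data.frame(table)
  viol <- list()
  add <- function(row, type, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, individual_id = df$individual_id[row],
      call_id = df$call_id[row], type = type, detail = detail,
      stringsAsFactors = FALSE)
  }
  pfc <- as.matrix(df[.pfc_cols])
  for (i in seq_len(nrow(df))) {
    v <- pfc[i, ]
    if (any(!is.finite(v)) || !is.finite(df$duration_s[i])) {
      add(i, "nonfinite", "non-finite feature value")
    }
    oob <- v[is.finite(v) & (v < freq_band_hz[1] | v > freq_band_hz[2])]
    if (length(oob)) {
      add(i, "out_of_band",
          sprintf("%d PFC value(s) outside [%g, %g] Hz", length(oob),
                  freq_band_hz[1], freq_band_hz[2]))
    }
  }
  key <- paste(df$individual_id, df$call_id, sep = "\r")
  for (i in which(duplicated(key))) add(i, "duplicate_call_id", key[i])
  counts <- as.data.frame(table(individual_id = df$individual_id),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n_calls"
  for (id in counts$individual_id[counts$n_calls < 2]) {
    row <- which(df$individual_id == id)[1]
    add(row, "insufficient_calls", "individual has < 2 calls")
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(), individual_id = character(),
               call_id = character(), type = character(),
               detail = character(), stringsAsFactors = FALSE)
  structure(list(violations = violations, call_counts = counts,
                 freq_band_hz = freq_band_hz),
            class = "call_validation")
}

#' @export
print.call_validation <- function(x, ...) {
  cat(sprintf("call table validation: %d violation(s), %d individual(s)\n",
              nrow(x$violations), nrow(x$call_counts)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
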