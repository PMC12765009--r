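#' Raw peak-frequency contour of one call
#'
#' Container for a variable-length peak-frequency contour (PFC) as exported
#' per spectrogram slice by sound-analysis software: one frequency sample
#' per slice, uniformly spaced in time across the selection.
#'
#' @param selection_id Identifier of the selection (call).
#' @param begin_s,end_s Selection start and end time in seconds;
#'   `end_s > begin_s >= 0`.
#' @param freqs_hz Numeric vector (length >= 2) of peak-frequency samples in
#'   Hz, all finite and positive, uniformly spaced over `[begin_s, end_s]`.
#' @return An object of class `raw_contour`.
#' @examples
#' rc <- raw_contour("sel1", 0, 0.4, seq(600, 1000, length.out = 20))
#' resample_evenly(rc)
#' @export
raw_contour <- function(selection_id, begin_s, end_s, freqs_hz) {
  if (!is.numeric(begin_s) || !is.numeric(end_s) || length(begin_s) != 1L ||
      length(end_s) != 1L || !is.finite(begin_s) || !is.finite(end_s)) {
    stop("begin_s and end_s must be single finite numbers")
  }
  if (begin_s < 0) stop("begin_s must be >= 0")
  if (end_s <= begin_s) stop("end_s must be greater than begin_s")
  freqs_hz <- as.numeric(freqs_hz)
  if (length(freqs_hz) < 2L) {
    stop("a contour needs at least 2 frequency samples")
  }
  if (!all(is.finite(freqs_hz)) || any(freqs_hz <= 0)) {
    stop("contour frequencies must be finite and positive")
  }
  structure(
    list(selection_id = as.character(selection_id),
         begin_s = begin_s, end_s = end_s, freqs_hz = freqs_hz),
    class = "raw_contour"
  )
}

#' Resample a contour at evenly spaced time points
#'
#' Evaluates a peak-frequency contour by linear interpolation at `k` time
#' points spread evenly over the call, endpoints included (sample `i` sits at
#' time fraction `(i-1)/(k-1)` of the call). This is the time-normalized even
#' sampling that makes calls of different durations comparable: every call is
#' reduced to the same number of contour points regardless of how many
#' spectrogram slices it spanned. The first and last returned values equal
#' the contour's own first and last samples, and interpolated values never
#' leave the range of the original samples.
#'
#' @param contour A [raw_contour()] object, or a plain numeric vector of
#'   contour samples assumed uniformly spaced in time.
#' @param k Number of output samples (default 10, the contour length used
#'   throughout the package); must be >= 2.
#' @return Numeric vector of `k` frequencies in Hz.
#' @examples
#' resample_evenly(c(600, 700, 1000), k = 5)
#' @export
resample_evenly <- function(contour, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be a single integer >= 2")
  }
  k <- as.integer(k)
  freqs <- if (inherits(contour, "raw_contour")) contour$freqs_hz else as.numeric(contour)
  n <- length(freqs)
  if (n < 2L) stop("a contour needs at least 2 frequency samples")
  if (!all(is.finite(freqs))) stop("contour frequencies must be finite")
  approx(x = seq(0, 1, length.out = n), y = freqs,
         xout = seq(0, 1, length.out = k))$y
}

#' Build the 11-dimensional call feature vector
#'
#' Assembles the measurement vector used by all downstream metrics:
#' positions 1-10 are the contour resampled to 10 evenly spread
#' peak-frequency values (Hz), position 11 is the call duration in seconds
#' (`end_s - begin_s`).
#'
#' @param contour A [raw_contour()] object.
#' @return Named numeric vector of length 11 (`pfc_01`..`pfc_10`,
#'   `duration_s`).
#' @export
build_feature_vector <- function(contour) {
  if (!inherits(contour, "raw_contour")) {
    stop("build_feature_vector() expects a raw_contour object")
  }
  v <- c(resample_evenly(contour, 10), contour$end_s - contour$begin_s)
  names(v) <- .feature_cols
  v
}
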