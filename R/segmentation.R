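# Preliminary stance/swing segmentation from the jerk magnitude.
#
# The comprehensive change rate of acceleration (discrete jerk magnitude) is
# near zero while the foot rests on the ground and large while it moves; a
# threshold relative to the record maximum of the smoothed jerk splits the
# timeline into flat (foot supported) and non-flat phases.

#' Comprehensive change rate of acceleration (jerk magnitude)
#'
#' The Euclidean norm of the forward differences of the three acceleration
#' axes: `out[i] = sqrt(dax^2 + day^2 + daz^2)` with `d` the sample-to-sample
#' difference. The output has length `N - 1`.
#'
#' @param ax,ay,az equal-length acceleration series, `N >= 2`.
#' @return non-negative numeric vector of length `N - 1`.
#' @export
jerk_magnitude <- function(ax, ay, az) {
  if (!(length(ax) == length(ay) && length(ay) == length(az))) {
    stop("ax, ay, az must have equal length", call. = FALSE)
  }
  if (length(az) < 2L) stop("need at least 2 samples", call. = FALSE)
  sqrt(diff(ax)^2 + diff(ay)^2 + diff(az)^2)
}

#' Smooth the jerk magnitude with a trailing window
#'
#' Causal moving average over the trailing window `[j - W + 1, j]` with
#' `W = round(window_ms * fs / 1000)` samples; the leading boundary uses the
#' truncated available window.
#'
#' @param ja jerk magnitude series.
#' @param fs sampling frequency (Hz).
#' @param window_ms smoothing window in milliseconds (default 30, i.e. 30
#'   samples at 1000 Hz).
#' @return smoothed series of the same length.
#' @export
smooth_jerk <- function(ja, fs, window_ms = 30) {
  if (!is.numeric(window_ms) || window_ms <= 0) {
    stop("`window_ms` must be positive", call. = FALSE)
  }
  w <- max(1L, as.integer(round(window_ms * fs / 1000)))
  n <- length(ja)
  cs <- cumsum(ja)
  lo <- pmax(seq_len(n) - w, 0L)               # index before window start
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

.intervals_from_binary <- function(binary) {
  r <- rle(binary)
  ends <- cumsum(r$lengths)            # 1-based inclusive ends
  starts <- ends - r$lengths + 1L
  data.frame(start = starts - 1L, end = ends,  # 0-based half-open
             value = r$values)
}

.new_segmentation <- function(binary, threshold_used, r, fs) {
  iv <- .intervals_from_binary(binary)
  structure(list(binary = binary,
                 flat_intervals = iv[iv$value == 0L, c("start", "end")],
                 nonflat_intervals = iv[iv$value == 1L, c("start", "end")],
                 threshold_used = threshold_used, r = r, fs = fs),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "<phase_segmentation> %d samples, %d flat / %d non-flat intervals, threshold %.4g (r = %g)\n",
    length(x$binary), nrow(x$flat_intervals), nrow(x$nonflat_intervals),
    x$threshold_used, x$r))
  invisible(x)
}

#' Binarize the smoothed jerk against an adaptive threshold
#'
#' A sample is non-flat (1) when the smoothed jerk exceeds
#' `thS = r * max(ja)`, flat (0) otherwise. Flat and non-flat intervals are
#' derived by run-length encoding; intervals are 0-based half-open
#' `[start, end)` sample ranges.
#'
#' @param ja smoothed jerk series (non-negative, non-empty).
#' @param r relative threshold, `0 < r < 1` (default 0.05).
#' @param fs sampling frequency (Hz), carried for downstream conversions.
#' @return object of class `phase_segmentation` with fields `binary`,
#'   `flat_intervals`, `nonflat_intervals`, `threshold_used`, `r`, `fs`.
#' @export
binarize_jerk <- function(ja, r = 0.05, fs = NA_real_) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("`r` must be in (0, 1)", call. = FALSE)
  }
  if (!length(ja)) stop("`ja` must be non-empty", call. = FALSE)
  if (any(ja < 0)) stop("`ja` must be non-negative", call. = FALSE)
  m <- max(ja)
  if (m == 0) {
    stop("degenerate signal: max of smoothed jerk is 0, threshold undefined",
         call. = FALSE)
  }
  th <- r * m
  binary <- as.integer(ja > th)
  .new_segmentation(binary, th, r, fs)
}

#' Absorb implausibly short segments
#'
#' Intervals shorter than `min_ms` (except the first and last, which may be
#' boundary-truncated) are merged into their neighbours by flipping their
#' phase, shortest first, until none remain. The flat/non-flat tiling of the
#' timeline is preserved.
#'
#' @param seg a `phase_segmentation`.
#' @param min_ms minimum plausible phase duration in milliseconds
#'   (default 100; single-support phases in steady walking last well over
#'   100 ms).
#' @return a new `phase_segmentation`.
#' @export
filter_short_segments <- function(seg, min_ms = 50) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (min_ms < 0) stop("`min_ms` must be >= 0", call. = FALSE)
  if (is.na(seg$fs)) stop("segmentation has no sampling rate", call. = FALSE)
  min_len <- as.integer(round(min_ms * seg$fs / 1000))
  binary <- seg$binary
  repeat {
    r <- rle(binary)
    k <- length(r$lengths)
    if (k <= 2L) break
    interior <- 2:(k - 1L)
    short <- interior[r$lengths[interior] < min_len]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- 1L - r$values[i]
    binary <- inverse.rle(r)
  }
  .new_segmentation(binary, seg$threshold_used, seg$r, seg$fs)
}

#' Segment a recording into flat and non-flat phases
#'
#' Composition of [jerk_magnitude()], [smooth_jerk()], [binarize_jerk()] and
#' [filter_short_segments()]. The recording should already be denoised (see
#' [denoise_signal()]); jerk is computed on all three axes.
#'
#' @param rec an [accel_recording()] (denoised).
#' @param r relative threshold for [binarize_jerk()].
#' @param window_ms smoothing window (ms).
#' @param min_segment_ms minimum plausible phase duration (ms).
#' @return a `phase_segmentation` whose `binary` has length `N - 1`.
#' @export
segment_phases <- function(rec, r = 0.05, window_ms = 30,
                           min_segment_ms = 100) {
  stopifnot(inherits(rec, "accel_recording"))
  ja <- smooth_jerk(jerk_magnitude(rec$ax, rec$ay, rec$az), rec$fs, window_ms)
  filter_short_segments(binarize_jerk(ja, r, rec$fs), min_segment_ms)
}
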