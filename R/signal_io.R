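# CSV input/output for recordings, event sequences and displacement series.
#
# Conventions used throughout the package: comma-separated files with one
# header line and '.' decimal separator; sample indices are 0-based; times
# are in seconds; intervals are half-open [start, end).

.sites <- c("heel", "toe")
.event_labels <- c("HS", "TS", "HO", "TO")

#' Construct an accelerometer recording
#'
#' A uniformly sampled tri-axial acceleration series for one sensor site.
#' The vertical axis is `az`; sample `i` (0-based) has time `t0 + i/fs`.
#'
#' @param ax,ay,az equal-length numeric acceleration series in m/s^2.
#' @param fs sampling frequency in Hz (> 0).
#' @param site `"heel"` or `"toe"`.
#' @param t0 start time in seconds.
#' @return object of class `accel_recording`.
#' @export
accel_recording <- function(ax, ay, az, fs, site = c("heel", "toe"), t0 = 0) {
  site <- match.arg(site)
  if (!(length(ax) == length(ay) && length(ay) == length(az))) {
    stop("ax, ay, az must have equal length", call. = FALSE)
  }
  if (length(az) < 2L) stop("a recording needs at least 2 samples",
                            call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    stop("acceleration values must all be finite", call. = FALSE)
  }
  structure(list(ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), fs = fs, site = site, t0 = t0),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> site=%s n=%d fs=%g Hz duration=%.3f s\n",
              x$site, length(x$az), x$fs, length(x$az) / x$fs))
  invisible(x)
}

#' @export
length.accel_recording <- function(x) length(x$az)

# Times (s) of the recording's samples.
rec_times <- function(rec) rec$t0 + (seq_along(rec$az) - 1L) / rec$fs

.read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) < 2L) stop("need at least 2 data rows in ", path,
                           call. = FALSE)
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    na_in <- which(is.na(num[[j]]))
    if (length(na_in)) {
      stop(sprintf("parse error in %s: non-numeric value '%s' at data row %d (column '%s')",
                   path, raw[na_in[1L], j], na_in[1L], names(raw)[j]),
           call. = FALSE)
    }
  }
  as.data.frame(num, check.names = FALSE)
}

#' Read a recording from CSV
#'
#' Accepts 3 numeric columns (`ax, ay, az`) or 4 with a leading time column.
#' When a time column is present its spacing must be uniform and consistent
#' with `fs` within 1 percent relative tolerance.
#'
#' @param path CSV file path.
#' @param site sensor site, `"heel"` or `"toe"`.
#' @param fs sampling frequency in Hz.
#' @return an [accel_recording()].
#' @export
read_recording <- function(path, site = c("heel", "toe"), fs) {
  site <- match.arg(site)
  df <- .read_numeric_csv(path)
  if (!ncol(df) %in% c(3L, 4L)) {
    stop("expected 3 or 4 numeric columns in ", path, ", found ", ncol(df),
         call. = FALSE)
  }
  t0 <- 0
  if (ncol(df) == 4L) {
    tm <- df[[1L]]
    dt <- diff(tm)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * mean(dt)) {
      stop("sampling error in ", path, ": time column is not uniformly spaced",
           call. = FALSE)
    }
    if (abs(mean(dt) - 1 / fs) > 0.01 / fs) {
      stop("sampling error in ", path, ": time step ", signif(mean(dt), 6),
           " s is inconsistent with fs = ", fs, " Hz", call. = FALSE)
    }
    t0 <- tm[1L]
    df <- df[-1L]
  }
  accel_recording(df[[1L]], df[[2L]], df[[3L]], fs = fs, site = site, t0 = t0)
}

#' Write a recording to CSV
#'
#' @param rec an [accel_recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(time = rec_times(rec), ax = rec$ax, ay = rec$ay,
                   az = rec$az)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a gait event sequence
#'
#' An ordered set of labelled gait events. Labels are `HS` (heel strike),
#' `TS` (toe strike), `HO` (heel off), `TO` (toe off); times are in seconds
#' and `sample_index` is the 0-based index in the source recording.
#'
#' @param label character vector of event labels.
#' @param time numeric event times (s).
#' @param sample_index integer 0-based sample indices.
#' @return a data frame of class `gait_events`, sorted by time.
#' @export
gait_events <- function(label = character(), time = numeric(),
                        sample_index = integer()) {
  if (!all(label %in% .event_labels)) {
    bad <- setdiff(unique(label), .event_labels)
    stop("unknown event label(s): ", paste(bad, collapse = ", "),
         "; expected HS, TS, HO, TO", call. = FALSE)
  }
  df <- data.frame(label = as.character(label), time = as.numeric(time),
                   sample_index = as.integer(sample_index),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gait_events", "data.frame")
  df
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d events", nrow(x)))
  if (nrow(x)) cat(sprintf(" spanning %.3f-%.3f s", min(x$time), max(x$time)))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read gait event sequences as CSV
#'
#' The round trip preserves labels exactly and times to better than 1e-9 s.
#'
#' @param events a [gait_events()] data frame.
#' @param path CSV file path.
#' @return `read_events` returns a [gait_events()] data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- data.frame(label = events$label,
                   time = format(events$time, digits = 15, trim = TRUE,
                                 scientific = FALSE),
                   sample_index = events$sample_index)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "integer"),
                        check.names = FALSE)
  if (!all(c("label", "time", "sample_index") %in% names(df))) {
    stop("format error in ", path,
         ": expected columns label, time, sample_index", call. = FALSE)
  }
  if (!all(df$label %in% .event_labels)) {
    bad <- setdiff(unique(df$label), .event_labels)
    stop("format error in ", path, ": unknown label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gait_events(df$label, df$time, df$sample_index)
}

#' Write / read a displacement series as CSV
#'
#' Two columns: `time` (s) and `displacement` (m). Used for motion-capture
#' style reference traces.
#'
#' @param time,displacement equal-length numeric vectors.
#' @param path CSV file path.
#' @return `read_displacement` returns a data frame with `time` and
#'   `displacement`.
#' @export
write_displacement <- function(time, displacement, path) {
  stopifnot(length(time) == length(displacement))
  df <- data.frame(time = time, displacement = displacement)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_displacement
#' @export
read_displacement <- function(path) {
  df <- .read_numeric_csv(path)
  if (ncol(df) != 2L) stop("expected 2 columns (time, displacement) in ",
                           path, call. = FALSE)
  names(df) <- c("time", "displacement")
  df
}
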