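# Gait event determination from detrended displacement troughs.
#
# Within (a margin-extended neighbourhood of) every flat phase, the strike
# event is the first displacement trough reached by a sharp drop, and the
# off event is the first trough after the strike that is left by a sharp
# rise. Heel troughs give HS/HO, toe troughs give TS/TO.

#' Find displacement troughs with local slope annotations
#'
#' Locates every strict local minimum of `d` inside the half-open 0-based
#' sample interval and annotates it with the mean slope over the preceding
#' and following `slope_window_ms` (truncated at the record boundary).
#'
#' @param d displacement series (m).
#' @param interval length-2 vector, 0-based half-open `[start, end)`; must
#'   cover at least 3 samples after clipping to the record.
#' @param fs sampling frequency (Hz).
#' @param slope_window_ms slope estimation window (ms), > 0 (default 50).
#' @return data frame with `sample_index` (0-based), `value`, `pre_slope`,
#'   `post_slope` (m/s), ordered by index.
#' @export
find_troughs <- function(d, interval, fs, slope_window_ms = 50) {
  if (slope_window_ms <= 0) stop("`slope_window_ms` must be > 0",
                                 call. = FALSE)
  n <- length(d)
  lo <- max(0L, as.integer(interval[1L]))
  hi <- min(n, as.integer(interval[2L]))
  if (hi - lo < 3L) stop("interval must span at least 3 samples",
                         call. = FALSE)
  w <- max(1L, as.integer(round(slope_window_ms * fs / 1000)))
  # 1-based candidate indices: need both neighbours inside the record and the
  # 0-based index inside [lo, hi)
  ii <- seq.int(max(lo, 1L) + 1L, min(hi, n - 1L))
  if (!length(ii)) return(data.frame(sample_index = integer(),
                                     value = numeric(), pre_slope = numeric(),
                                     post_slope = numeric()))
  is_min <- d[ii] < d[ii - 1L] & d[ii] < d[ii + 1L]
  idx <- ii[is_min]
  pre_n <- pmin(w, idx - 1L)
  post_n <- pmin(w, length(d) - idx)
  data.frame(
    sample_index = idx - 1L,
    value = d[idx],
    pre_slope = (d[idx] - d[idx - pre_n]) / (pre_n / fs),
    post_slope = (d[idx + post_n] - d[idx]) / (post_n / fs))
}

.detection_failure <- function(msg, candidates) {
  structure(class = c("gait_detection_failure", "error", "condition"),
            list(message = msg, call = NULL, candidates = candidates))
}

#' Select the strike event among trough candidates
#'
#' Returns the first candidate whose preceding mean slope is at most
#' `-drop_slope_thresh` (the trough the displacement "drops sharply" into).
#'
#' @param candidates data frame from [find_troughs()], non-empty.
#' @param drop_slope_thresh sharp-drop threshold (m/s, default 0.05).
#' @return one row of `candidates`.
#' @export
detect_strike <- function(candidates, drop_slope_thresh = 0.05) {
  if (!nrow(candidates)) stop("no trough candidates", call. = FALSE)
  hit <- which(candidates$pre_slope <= -drop_slope_thresh)
  if (!length(hit)) {
    stop(.detection_failure(
      "no trough candidate meets the sharp-drop criterion", candidates))
  }
  candidates[hit[1L], , drop = FALSE]
}

#' Select the off event among trough candidates
#'
#' Returns the first candidate after `after_index` whose following mean slope
#' is at least `+rise_slope_thresh` (the trough the displacement "rises
#' sharply" out of). A candidate reached by a rise steeper than
#' `max_pre_slope` is not a trough of the stance plateau but a notch on an
#' already-rising flank, and is skipped: the foot is on the ground before it
#' lifts, so the displacement ahead of a genuine off trough is flat or
#' falling.
#'
#' @param candidates data frame from [find_troughs()], non-empty.
#' @param rise_slope_thresh sharp-rise threshold (m/s, default 0.05).
#' @param after_index 0-based sample index the candidate must follow
#'   (typically the strike index).
#' @param max_pre_slope upper bound on the preceding mean slope
#'   (m/s; default `rise_slope_thresh`).
#' @return one row of `candidates`.
#' @export
detect_off <- function(candidates, rise_slope_thresh = 0.05,
                       after_index = -1L,
                       max_pre_slope = rise_slope_thresh) {
  if (!nrow(candidates)) stop("no trough candidates", call. = FALSE)
  hit <- which(candidates$sample_index > after_index &
                 candidates$post_slope >= rise_slope_thresh &
                 candidates$pre_slope < max_pre_slope)
  if (!length(hit)) {
    stop(.detection_failure(
      "no trough candidate meets the sharp-rise criterion", candidates))
  }
  candidates[hit[1L], , drop = FALSE]
}

# Strike/off pair for every usable flat interval of one site.
.detect_site_events <- function(disp, seg, labels, config) {
  ev <- config$events
  fs <- disp$fs
  n <- length(disp$detrended)
  margin <- as.integer(round(ev$search_margin_ms * fs / 1000))
  flats <- seg$flat_intervals
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(flats))) {
    # boundary-truncated intervals belong to incomplete cycles
    if (flats$start[k] <= 0L || flats$end[k] >= length(seg$binary)) next
    interval <- c(flats$start[k] - margin, flats$end[k] + margin)
    res <- tryCatch({
      cand <- find_troughs(disp$detrended, interval, fs, ev$slope_window_ms)
      strike <- detect_strike(cand, ev$drop_slope_thresh)
      off <- detect_off(cand, ev$rise_slope_thresh, strike$sample_index)
      list(strike = strike$sample_index, off = off$sample_index)
    }, gait_detection_failure = function(e) NULL, error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- res
  }
  strikes <- vapply(out, `[[`, integer(1), "strike")
  offs <- vapply(out, `[[`, integer(1), "off")
  list(events = gait_events(
         label = rep(labels, each = length(strikes)),
         time = c(strikes, offs) / fs,
         sample_index = c(strikes, offs)),
       skipped = skipped)
}

#' Determine all four gait events
#'
#' For every interior flat interval of the heel segmentation one HS and one
#' HO are detected from the heel displacement, and likewise TS and TO from
#' the toe; each search interval is the flat interval extended by
#' `search_margin_ms` on both sides, because the displacement trough at
#' strike can precede the jerk-quiet region. Cycles whose assembled
#' quadruple violates the physiological order HS <= TS <= HO <= TO are
#' dropped with a warning, as are intervals yielding no valid strike/off
#' pair.
#'
#' @param heel_disp,toe_disp [displacement_trace()]s.
#' @param heel_seg,toe_seg matching `phase_segmentation`s.
#' @param config a [gait_config()].
#' @return a [gait_events()] data frame; attribute `skipped` counts
#'   discarded intervals/cycles.
#' @export
detect_all <- function(heel_disp, toe_disp, heel_seg, toe_seg,
                       config = gait_config()) {
  stopifnot(inherits(heel_disp, "displacement_trace"),
            inherits(toe_disp, "displacement_trace"))
  if (!nrow(heel_seg$flat_intervals) || !nrow(toe_seg$flat_intervals)) {
    warning("no flat interval to search; returning empty event sequence")
    return(gait_events())
  }
  heel <- .detect_site_events(heel_disp, heel_seg, c("HS", "HO"), config)
  toe <- .detect_site_events(toe_disp, toe_seg, c("TS", "TO"), config)
  skipped <- heel$skipped + toe$skipped

  hs <- heel$events[heel$events$label == "HS", ]
  ho <- heel$events[heel$events$label == "HO", ]
  ts <- toe$events[toe$events$label == "TS", ]
  to <- toe$events[toe$events$label == "TO", ]

  # assemble cycles anchored at each HS; enforce HS <= TS <= HO <= TO
  rows <- list()
  hs_times <- c(hs$time, Inf)
  for (k in seq_len(nrow(hs))) {
    t_hs <- hs$time[k]
    t_next <- hs_times[k + 1L]
    pick <- function(df, t_min) {
      j <- which(df$time >= t_min & df$time < t_next)
      if (length(j)) df[j[1L], , drop = FALSE] else NULL
    }
    e_ts <- pick(ts, t_hs)
    if (is.null(e_ts)) { skipped <- skipped + 1L; next }
    e_ho <- pick(ho, e_ts$time)
    if (is.null(e_ho)) { skipped <- skipped + 1L; next }
    e_to <- pick(to, e_ho$time)
    if (is.null(e_to)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- rbind(hs[k, ], e_ts, e_ho, e_to)
  }
  if (skipped > 0L) {
    warning(skipped, " interval(s)/cycle(s) yielded no valid ordered ",
            "strike/off events and were skipped")
  }
  if (!length(rows)) return(gait_events())
  all_ev <- do.call(rbind, rows)
  out <- gait_events(all_ev$label, all_ev$time, all_ev$sample_index)
  attr(out, "skipped") <- skipped
  out
}
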