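# End-to-end detection pipeline.

# Denoise all three axes of a recording with the modulus-maxima method.
.denoise_recording <- function(rec, config) {
  dn <- config$denoise
  f <- function(x) denoise_signal(x, levels = dn$levels,
                                  beta_threshold = dn$beta_threshold,
                                  max_iter = dn$max_iter, tol = dn$tol)
  accel_recording(f(rec$ax), f(rec$ay), f(rec$az), fs = rec$fs,
                  site = rec$site, t0 = rec$t0)
}

#' Detect gait events from heel and toe recordings
#'
#' Runs the full pipeline: modulus-maxima denoising of every axis, gravity
#' removal from the vertical axis, jerk-threshold phase segmentation,
#' frequency-domain double integration with wavelet detrending, and
#' trough-based determination of HS, TS, HO and TO.
#'
#' @param heel_rec,toe_rec [accel_recording()]s for the heel and toe sites
#'   (same sampling rate).
#' @param config a [gait_config()].
#' @return list of class `gait_detection`: `events` (a [gait_events()]),
#'   per-site `segmentation` and `displacement`, and `config`.
#' @examples
#' trial <- make_trial(gait_params(n_cycles = 3, seed = 42))
#' det <- detect_gait_events(trial$heel_rec, trial$toe_rec)
#' det$events
#' @export
detect_gait_events <- function(heel_rec, toe_rec, config = gait_config()) {
  stopifnot(inherits(heel_rec, "accel_recording"),
            inherits(toe_rec, "accel_recording"))
  if (heel_rec$fs != toe_rec$fs) {
    stop("heel and toe recordings must share a sampling rate", call. = FALSE)
  }
  sg <- config$segmentation

  process_site <- function(rec) {
    den <- .denoise_recording(rec, config)
    den$az <- remove_gravity(den$az)
    seg <- segment_phases(den, r = sg$r, window_ms = sg$window_ms,
                          min_segment_ms = sg$min_segment_ms)
    disp <- acceleration_to_displacement(den, config, denoised = TRUE)
    list(seg = seg, disp = disp)
  }

  heel <- process_site(heel_rec)
  toe <- process_site(toe_rec)
  events <- detect_all(heel$disp, toe$disp, heel$seg, toe$seg, config)
  structure(list(events = events,
                 heel = heel, toe = toe, config = config),
            class = "gait_detection")
}

#' @export
print.gait_detection <- function(x, ...) {
  cat(sprintf(
    "<gait_detection> %d events (%d cycles); heel threshold %.4g, toe threshold %.4g\n",
    nrow(x$events), nrow(x$events) %/% 4L,
    x$heel$seg$threshold_used, x$toe$seg$threshold_used))
  invisible(x)
}
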