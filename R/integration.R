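# Frequency-domain double integration of vertical acceleration.

#' Double integration in the frequency domain
#'
#' Converts acceleration to displacement by dividing the DFT of the signal by
#' \eqn{(j\omega_k)^2} and inverse transforming, with
#' \eqn{\omega_k = 2\pi k f_s / N} for \eqn{k \le N/2} and conjugate-symmetric
#' negative frequencies above. The DC bin (where the operator is singular)
#' and all bins below `highpass_hz` are zeroed, which suppresses the unbounded
#' near-DC amplification of the \eqn{1/\omega^2} operator.
#'
#' @param az zero-mean vertical acceleration (m/s^2), `length >= 8`.
#' @param fs sampling frequency (Hz).
#' @param highpass_hz cutoff below which bins are zeroed; must satisfy
#'   `0 <= highpass_hz < fs/2` (default 0.1 Hz).
#' @return real displacement series (m) of the same length.
#' @examples
#' fs <- 1000; t <- seq(0, 2 - 1/fs, by = 1/fs); w <- 2 * pi * 2
#' d <- double_integrate_fft(-w^2 * sin(w * t), fs)  # recovers sin(w t)
#' @export
double_integrate_fft <- function(az, fs, highpass_hz = 0.1) {
  n <- length(az)
  if (n < 8L) stop("need at least 8 samples", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (highpass_hz < 0 || highpass_hz >= fs / 2) {
    stop("`highpass_hz` must be in [0, fs/2)", call. = FALSE)
  }
  A <- stats::fft(az)
  k <- 0:(n - 1L)
  freq <- ifelse(k <= n / 2, k, k - n) * fs / n   # signed bin frequency (Hz)
  w <- 2 * pi * freq
  keep <- abs(freq) >= max(highpass_hz, .Machine$double.eps) & w != 0
  H <- complex(real = numeric(n), imaginary = numeric(n))
  H[keep] <- A[keep] / (-w[keep]^2)               # division by (j w)^2
  Re(stats::fft(H, inverse = TRUE)) / n
}

#' Displacement trace container
#'
#' Vertical displacement from double integration, before (`raw`) and after
#' (`detrended`) wavelet trend removal.
#'
#' @param site `"heel"` or `"toe"`.
#' @param fs sampling frequency (Hz).
#' @param raw,detrended equal-length displacement series (m).
#' @return object of class `displacement_trace`.
#' @export
displacement_trace <- function(site, fs, raw, detrended) {
  stopifnot(length(raw) == length(detrended))
  structure(list(site = site, fs = fs, raw = raw, detrended = detrended),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(
    "<displacement_trace> site=%s n=%d fs=%g Hz range [%.1f, %.1f] mm\n",
    x$site, length(x$raw), x$fs, 1000 * min(x$detrended),
    1000 * max(x$detrended)))
  invisible(x)
}

#' Vertical displacement from an acceleration recording
#'
#' Full conversion for one sensor site: (optionally) modulus-maxima
#' denoising, gravity removal, frequency-domain double integration, then
#' wavelet detrending of the integrated displacement. The detrended series
#' additionally has its residual sample mean removed.
#'
#' @param rec an [accel_recording()].
#' @param config a [gait_config()] list (integration and denoise sections
#'   are used).
#' @param denoised set `TRUE` when `rec` has already been denoised upstream.
#' @return a [displacement_trace()].
#' @export
acceleration_to_displacement <- function(rec, config = gait_config(),
                                         denoised = FALSE) {
  stopifnot(inherits(rec, "accel_recording"))
  az <- rec$az
  if (!denoised) {
    dn <- config$denoise
    az <- denoise_signal(az, levels = dn$levels,
                         beta_threshold = dn$beta_threshold,
                         max_iter = dn$max_iter, tol = dn$tol)
  }
  az <- remove_gravity(az)
  ig <- config$integration
  raw <- double_integrate_fft(az, rec$fs, ig$highpass_hz)
  det <- detrend_wavelet(raw, levels = ig$detrend_levels,
                         basis = ig$detrend_basis,
                         soft_details = identical(ig$soft_threshold_mode,
                                                  "ca_and_details"))
  det <- det - mean(det)
  displacement_trace(rec$site, rec$fs, raw, det)
}
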