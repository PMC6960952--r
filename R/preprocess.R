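#' Remove the gravity component from vertical acceleration
#'
#' Subtracts the mean over the whole continuous record from the vertical
#' acceleration series, removing the static gravity offset (and any constant
#' sensor bias) before integration. The mean is taken over the entire record,
#' not per segment.
#'
#' @param az numeric vertical acceleration series (m/s^2), non-empty and
#'   finite.
#' @return `az - mean(az)`, a zero-mean series of the same length.
#' @examples
#' remove_gravity(c(9.81, 9.81, 9.81))  # -> 0 0 0
#' @export
remove_gravity <- function(az) {
  if (length(az) < 1L) stop("`az` must be non-empty", call. = FALSE)
  if (!all(is.finite(az))) stop("`az` must be finite", call. = FALSE)
  az - mean(az)
}
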