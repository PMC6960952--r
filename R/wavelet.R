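# Decimated orthogonal wavelet transform used for displacement detrending.
#
# No assumption is made about signal length: the input is symmetric-extended
# once to a dyadic-multiple length and a periodized transform (which is
# exactly invertible) is applied to the extended signal; results are cropped
# back to the original support.

# Orthonormal scaling (lowpass decomposition) filters. These are the standard
# published Daubechies / symlet coefficients.
.wt_dec_lo <- list(
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108,
          0.00055384220116149613, -0.03158203931748603,
          0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983,
          0.31525035170919763, 0.75113390802109536,
          0.49462389039845306, 0.11154074335010947),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054,
           -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037,
           -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609))

.wt_filters <- function(basis) {
  h <- .wt_dec_lo[[basis]]
  if (is.null(h)) {
    stop("unknown wavelet basis '", basis, "'; available: ",
         paste(names(.wt_dec_lo), collapse = ", "), call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)  # quadrature mirror highpass
  list(h = h, g = g)
}

# One periodized analysis step. x must have even length.
.dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)  # 0-based even positions
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of .dwt_step (adjoint; exact because the filter bank is orthonormal).
.idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    contrib <- h[m] * a + g[m] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# Point-symmetric (odd, slope-preserving) extension by `pad` samples per
# side; pad <= n - 1. Reflecting through the endpoint value keeps the signal
# C1 at the boundary, so a trending record does not acquire a fold there --
# essential when the deep approximation band is later zeroed.
.sym_extend <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1L] - x[seq.int(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq.int(n - 1L, n - pad)]
  c(left, x, right)
}

#' Multilevel wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus one approximation band
#' using an orthogonal wavelet. Boundaries are handled by symmetric extension
#' followed by a periodized transform, so reconstruction with [wave_rec()] is
#' exact to machine precision.
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param levels number of decomposition levels.
#' @param basis wavelet basis name: one of `"sym8"`, `"db6"`, `"db2"`.
#' @return A list of class `wave_dec` with elements `a` (deepest
#'   approximation), `d` (list of detail bands, coarsest first), and the
#'   geometry needed for reconstruction.
#' @seealso [wave_rec()], [detrend_wavelet()]
#' @export
wave_dec <- function(x, levels, basis = "sym8") {
  stopifnot(is.numeric(x), levels >= 1)
  n <- length(x)
  if (n < 2^levels) {
    stop("signal of length ", n, " is too short for ", levels,
         " decomposition levels (needs >= ", 2^levels,
         "); reduce `levels`", call. = FALSE)
  }
  filt <- .wt_filters(basis)
  pad <- min(n, (length(filt$h) - 1L) * 2^levels)
  xe <- .sym_extend(x, pad)
  pad <- (length(xe) - n) / 2L
  # round up to a multiple of 2^levels
  m <- length(xe)
  target <- 2^levels * ceiling(m / 2^levels)
  if (target > m) xe <- c(xe, rev(xe)[seq_len(target - m)])
  a <- xe
  d <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, filt$h, filt$g)
    a <- s$a
    d[[levels - j + 1L]] <- s$d  # store coarsest first
  }
  structure(list(a = a, d = d, n = n, pad = pad, m = target,
                 levels = levels, basis = basis),
            class = "wave_dec")
}

#' Multilevel wavelet reconstruction
#'
#' Inverts [wave_dec()]; `wave_rec(wave_dec(x, ...))` reproduces `x` to
#' machine precision.
#'
#' @param dec a `wave_dec` object (possibly with modified coefficients).
#' @return numeric vector of the original length.
#' @export
wave_rec <- function(dec) {
  stopifnot(inherits(dec, "wave_dec"))
  filt <- .wt_filters(dec$basis)
  a <- dec$a
  for (j in seq_len(dec$levels)) {
    a <- .idwt_step(a, dec$d[[j]], filt$h, filt$g)
  }
  a[seq.int(dec$pad + 1L, dec$pad + dec$n)]
}

#' Remove the integration trend by wavelet decomposition
#'
#' Performs a deep wavelet decomposition of a displacement series and zeroes
#' the deepest approximation band, which carries the slowly varying trend
#' introduced by double integration of a non-zero-mean, drifting acceleration.
#' Optionally the detail bands are additionally soft-thresholded with the
#' universal threshold \eqn{\sigma \sqrt{2 \log N}}, \eqn{\sigma} estimated
#' from the median absolute deviation of the finest band.
#'
#' With the default 8 levels at 1000 Hz sampling, the removed approximation
#' band spans 0 to about 1.95 Hz.
#'
#' @param d numeric displacement vector, `length(d) >= 2^levels`.
#' @param levels decomposition depth (default 8).
#' @param basis wavelet basis, `"sym8"` (default) or `"db6"`.
#' @param soft_details logical; if `TRUE`, soft-threshold the detail bands as
#'   well. The default `FALSE` only zeroes the approximation band.
#' @return detrended numeric vector, same length as `d`.
#' @export
detrend_wavelet <- function(d, levels = 8, basis = "sym8",
                            soft_details = FALSE) {
  dec <- wave_dec(d, levels, basis)
  dec$a[] <- 0
  if (soft_details) {
    sigma <- stats::median(abs(dec$d[[levels]])) / 0.6745
    thr <- sigma * sqrt(2 * log(dec$m))
    dec$d <- lapply(dec$d, function(b) sign(b) * pmax(abs(b) - thr, 0))
  }
  wave_rec(dec)
}
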