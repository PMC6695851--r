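# IIR band-pass design and zero-phase filtering.
#
# The environment carries no DSP package, so the standard design chain is
# implemented here: analog Butterworth prototype -> low-pass-to-band-pass
# transform -> bilinear transform with frequency pre-warping. Only what the
# readout emulation needs (even total order, band-pass) is supported.

# polynomial (descending powers) from roots; real part returned
.poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Digital Butterworth band-pass coefficients
#'
#' @param order total filter order (even; the analog prototype has order/2)
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs/2`
#' @param fs sampling rate, Hz
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1)
#' @keywords internal
butter_bandpass <- function(order, f_lo, f_hi, fs) {
  if (order %% 2 != 0 || order < 2) stop_domain("total order must be even")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2))
    stop_domain("need 0 < f_lo < f_hi < fs/2")
  N <- order / 2
  # prototype poles on the unit circle, left half plane
  theta <- pi / 2 + (2 * seq_len(N) - 1) * pi / (2 * N)
  p_proto <- exp(1i * theta)
  # pre-warped edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)
  w2 <- fs2 * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole splits into two
  ps <- p_proto * bw / 2
  p_bp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  k_analog <- bw^N                      # N zeros at s = 0
  # bilinear transform
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c(rep(1, N), rep(-1, N))       # s = 0 and s = infinity images
  k_digital <- Re(k_analog * fs2^N / prod(fs2 - p_bp))
  b <- Re(.poly_from_roots(z_z)) * k_digital
  a <- Re(.poly_from_roots(z_p))
  list(b = b, a = a / a[1])
}

# direct-form IIR with zero initial conditions
.iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

#' Zero-phase (forward-backward) IIR filtering with odd-extension padding
#'
#' @param b,a transfer-function coefficients
#' @param x signal
#' @param padlen samples of odd reflection appended at both ends
#' @keywords internal
filtfilt_pad <- function(b, a, x, padlen = 3 * max(length(a), length(b))) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .iir_filter(b, a, ext)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Complex frequency response of a digital filter
#'
#' Direct evaluation of H(e^{j 2 pi f / fs}) from the coefficients; used as
#' the in-package oracle for the filter's attenuation contracts.
#'
#' @param b,a transfer-function coefficients
#' @param f frequencies in Hz (vector)
#' @param fs sampling rate, Hz
#' @return complex response at each frequency
#' @export
filter_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  num <- vapply(w, function(wi)
    sum(b * exp(-1i * wi * (seq_along(b) - 1))), complex(1))
  den <- vapply(w, function(wi)
    sum(a * exp(-1i * wi * (seq_along(a) - 1))), complex(1))
  num / den
}
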