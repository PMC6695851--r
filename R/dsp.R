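#' PPG waveform container
#'
#' @param samples numeric amplitude series (arbitrary units), length >= 2,
#'   all finite
#' @param fs sampling rate, Hz (> 0)
#' @param t0 start time, s
#' @return object of class `ppg_waveform`
#' @export
ppg_waveform <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_domain("samples must be a numeric vector of length >= 2")
  if (any(!is.finite(samples))) stop_domain("samples must all be finite")
  check_num(fs, "fs", positive = TRUE)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ppg_waveform")
}

#' @export
print.ppg_waveform <- function(x, ...) {
  cat(sprintf("<ppg_waveform: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Heart-rate estimate from the spectral peak of a PPG waveform
#'
#' The dominant periodicity in the cardiac band (0.5-3 Hz) is located on a
#' zero-padded magnitude spectrum and refined by parabolic interpolation of
#' the peak bin. A peak less than 4x the median band magnitude is treated as
#' noise and rejected.
#'
#' @param w [ppg_waveform()], at least 5 s long
#' @return heart rate in bpm
#' @export
estimate_heart_rate <- function(w) {
  stopifnot(inherits(w, "ppg_waveform"))
  x <- w$samples
  n <- length(x)
  if (n / w$fs < 5) stop_domain("waveform must be at least 5 s long")
  x <- x - mean(x)
  # light taper against leakage from drift
  x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n)))
  nfft <- 2^ceiling(log2(n * 4))
  spec <- Mod(stats::fft(c(x, rep(0, nfft - n))))[1:(nfft %/% 2)]
  freq <- (seq_along(spec) - 1) * w$fs / nfft
  band <- which(freq >= 0.5 & freq <= 3)
  if (length(band) < 3) stop_domain("cardiac band unresolvable at this fs/duration")
  mb <- spec[band]
  k <- which.max(mb)
  if (mb[k] <= 4 * stats::median(mb) || mb[k] <= 0)
    stop_domain("no spectral peak above the noise floor in 0.5-3 Hz")
  i <- band[k]
  # parabolic interpolation over the three bins around the peak
  delta <- 0
  if (i > 1 && i < length(spec)) {
    ym <- spec[i - 1]; y0 <- spec[i]; yp <- spec[i + 1]
    den <- ym - 2 * y0 + yp
    if (den != 0) delta <- 0.5 * (ym - yp) / den
  }
  f_hat <- (i - 1 + delta) * w$fs / nfft
  bpm <- 60 * f_hat
  max(min(bpm, 180), 30)
}

#' Band-pass filter specification
#'
#' @param f_lo,f_hi cutoffs in Hz
#' @param order filter order (the readout chain fixes 4)
#' @param family response family label
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(f_lo, f_hi, order = 4L, family = "butterworth") {
  check_num(f_lo, "f_lo", positive = TRUE)
  check_num(f_hi, "f_hi", positive = TRUE)
  if (f_lo >= f_hi) stop_domain("f_lo must be < f_hi")
  structure(list(order = as.integer(order), f_lo = f_lo, f_hi = f_hi,
                 family = family), class = "filter_spec")
}

#' Heart-rate-adaptive band-pass specification
#'
#' The hardware determines its cutoffs from the running heart rate; the
#' emulation uses half the cardiac frequency for the low edge and its 8th
#' harmonic for the high edge, clipped to the chain's design band of about
#' 0.2-10 Hz.
#'
#' @param hr_bpm heart rate in bpm, within \[30, 180\]
#' @return [filter_spec()] of order 4
#' @export
adaptive_filter_spec <- function(hr_bpm) {
  check_num(hr_bpm, "hr_bpm", positive = TRUE)
  if (hr_bpm < 30 || hr_bpm > 180)
    stop_domain("hr_bpm must lie in [30, 180]")
  hr_hz <- hr_bpm / 60
  f_lo <- min(max(0.5 * hr_hz, 0.2), 0.8)
  f_hi <- min(max(8 * hr_hz, 5), 10)
  filter_spec(f_lo, f_hi, order = 4L, family = "butterworth")
}

#' Apply the band-pass stage of the readout chain
#'
#' Zero-phase (forward-backward) application of the order-4 Butterworth
#' band-pass, removing both the DC/drift floor and mains interference while
#' leaving pulse morphology undistorted. Padding is sized to several periods
#' of the low cutoff so edge transients decay inside the pad.
#'
#' @param w [ppg_waveform()]
#' @param spec [filter_spec()]
#' @param equalize_hz optional frequency (Hz) at which the known zero-phase
#'   passband droop is divided out — typically the cardiac fundamental, so
#'   pulse amplitudes survive the low edge undistorted
#' @return [ppg_waveform()] holding the AC component
#' @export
apply_bandpass <- function(w, spec, equalize_hz = NULL) {
  stopifnot(inherits(w, "ppg_waveform"), inherits(spec, "filter_spec"))
  if (spec$f_hi >= w$fs / 2)
    stop_domain("high cutoff must be below the Nyquist frequency")
  ba <- butter_bandpass(spec$order, spec$f_lo, spec$f_hi, w$fs)
  padlen <- ceiling(3 * w$fs / spec$f_lo)
  y <- filtfilt_pad(ba$b, ba$a, w$samples, padlen = padlen)
  if (!is.null(equalize_hz)) {
    g <- Mod(filter_response(ba$b, ba$a, equalize_hz, w$fs))^2
    if (g > 0.1) y <- y / g  # never "equalize" deep in the stopband
  }
  ppg_waveform(y, w$fs, w$t0)
}

#' Stationary (DC) component of a PPG waveform
#'
#' Moving average over a window of exactly one beat period, with reflected
#' edge padding; the cardiac fundamental integrates to zero over the window
#' so only the slowly-varying floor survives.
#'
#' @param w [ppg_waveform()]
#' @param hr_bpm heart rate in bpm (sets the window length)
#' @return numeric DC series, same length as the input
#' @export
extract_dc <- function(w, hr_bpm) {
  stopifnot(inherits(w, "ppg_waveform"))
  check_num(hr_bpm, "hr_bpm", positive = TRUE)
  x <- w$samples
  n <- length(x)
  win <- max(2L, round(w$fs * 60 / hr_bpm))
  if (win > n) stop_domain("beat window longer than the signal")
  half <- win %/% 2
  rp <- win - half - 1L
  right <- if (rp > 0) x[(n - 1):(n - rp)] else numeric(0)
  ext <- c(x[(half + 1):2], x, right)
  cs <- cumsum(c(0, ext))
  (cs[(win + 1):(win + n)] - cs[1:n]) / win
}

#' Segment a filtered PPG waveform into beats
#'
#' Pulse feet are located as local minima of the AC component separated by a
#' refractory period of half the nominal beat. Beats with implausible
#' duration (outside 0.5-2x the nominal period) or implausible amplitude
#' (outside 0.25-4x the median beat amplitude) are flagged artifact and
#' excluded from downstream statistics.
#'
#' @param ac [ppg_waveform()] holding the filtered (AC) signal
#' @param hr_bpm nominal heart rate, bpm
#' @param dc optional DC series from [extract_dc()] on the raw waveform
#'   (same length); required to obtain per-beat perfusion indices
#' @return object of class `beat_series`: data.frame with columns `start`,
#'   `end` (sample indices), `ac`, `dc`, `pi`, `valid`
#' @export
segment_beats <- function(ac, hr_bpm, dc = NULL) {
  stopifnot(inherits(ac, "ppg_waveform"))
  x <- ac$samples
  n <- length(x)
  period <- ac$fs * 60 / hr_bpm
  refractory <- floor(0.5 * period)
  if (stats::sd(x) == 0 || n < 2 * period)
    stop_domain("insufficient signal: no pulsatile content to segment")
  # candidate feet: local minima in the lower quartile of the signal,
  # clear of the record edges where filter transients live
  guard <- max(1L, floor(0.1 * period))
  thr <- stats::quantile(x, 0.25, names = FALSE)
  idx <- (guard + 1):(n - guard)
  is_min <- x[idx] <= x[idx - 1] & x[idx] <= x[idx + 1] & x[idx] <= thr
  cand <- idx[is_min]
  if (length(cand) < 2)
    stop_domain("insufficient signal: no pulse feet found")
  # keep the deepest candidates subject to a refractory exclusion zone
  feet <- integer(0)
  taken_lo <- numeric(0); taken_hi <- numeric(0)
  for (i in cand[order(x[cand])]) {  # order() stable: ties to earlier sample
    if (any(i >= taken_lo & i <= taken_hi)) next
    feet <- c(feet, i)
    taken_lo <- c(taken_lo, i - refractory)
    taken_hi <- c(taken_hi, i + refractory)
  }
  feet <- sort(feet)
  if (length(feet) < 4)
    stop_domain("insufficient signal: fewer than 3 beats detected")
  start <- feet[-length(feet)]
  end <- feet[-1]
  dur <- (end - start)
  amp <- vapply(seq_along(start), function(k) {
    seg <- x[start[k]:end[k]]
    max(seg) - min(seg)
  }, numeric(1))
  dc_level <- if (is.null(dc)) rep(NA_real_, length(start)) else
    vapply(seq_along(start), function(k) mean(dc[start[k]:end[k]]), numeric(1))
  valid <- dur >= 0.5 * period & dur <= 2 * period
  # first and last beats sit on the zero-phase filter's edge transients
  if (length(valid) > 2) valid[c(1L, length(valid))] <- FALSE
  med_amp <- stats::median(amp[valid])
  if (is.finite(med_amp) && med_amp > 0)
    valid <- valid & amp >= 0.25 * med_amp & amp <= 4 * med_amp
  if (sum(valid) < 3)
    stop_domain("insufficient signal: fewer than 3 plausible beats")
  beats <- data.frame(start = start, end = end, ac = amp,
                      dc = dc_level, pi = amp / dc_level, valid = valid)
  structure(beats, class = c("beat_series", "data.frame"))
}

#' Perfusion-index extremes over the valid beats
#'
#' @param beats [segment_beats()] output with per-beat DC levels
#' @return list with `pi_max`, `pi_min`
#' @export
compute_pi_extrema <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  pis <- beats$pi[beats$valid]
  if (length(pis) < 3) stop_domain("fewer than 3 valid beats")
  if (any(!is.finite(pis)) || any(pis <= 0))
    stop_domain("per-beat PI undefined; was a DC series supplied?")
  list(pi_max = max(pis), pi_min = min(pis))
}

#' Programmable-gain amplifier and ADC emulation
#'
#' Maps the signal span affinely onto 5-95% of the reference voltage (the
#' gain the hardware PGA would choose to fill the converter's dynamic range)
#' and quantizes uniformly to `2^bits` levels.
#'
#' @param w [ppg_waveform()]
#' @param bits ADC resolution, in \[8, 24\]
#' @param vref reference voltage, volts
#' @return list with `waveform` (quantized voltages as [ppg_waveform()]),
#'   `codes` (integer codes), `gain`, `offset` such that
#'   `volts = gain * input + offset`
#' @export
simulate_pga_adc <- function(w, bits = 16L, vref = 3.3) {
  stopifnot(inherits(w, "ppg_waveform"))
  bits <- as.integer(bits)
  if (bits < 8L || bits > 24L) stop_domain("bits must lie in [8, 24]")
  x <- w$samples
  span <- max(x) - min(x)
  if (span == 0) stop_domain("zero-span input: PGA gain undefined")
  gain <- 0.9 * vref / span
  offset <- 0.05 * vref - gain * min(x)
  v <- gain * x + offset
  qmax <- 2^bits - 1
  codes <- pmin(pmax(round(v / vref * qmax), 0), qmax)
  vq <- codes / qmax * vref
  list(waveform = ppg_waveform(vq, w$fs, w$t0), codes = as.integer(codes),
       gain = gain, offset = offset)
}

#' Undo the PGA/ADC affine mapping
#'
#' @param adc output of [simulate_pga_adc()]
#' @return [ppg_waveform()] on the original amplitude scale
#' @export
adc_invert <- function(adc) {
  ppg_waveform((adc$waveform$samples - adc$offset) / adc$gain,
               adc$waveform$fs, adc$waveform$t0)
}
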