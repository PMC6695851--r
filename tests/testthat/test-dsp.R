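test_that("heart rate is recovered from the spectral peak", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  w <- ppg_waveform(1 + 0.02 * sin(2 * pi * 1.25 * t), fs)
  expect_equal(estimate_heart_rate(w), 75, tolerance = 0.015)  # +/- 1 bpm

  sw <- sample_waveform(list(pi_max = 0.02, pi_min = 0.015, hr = 60),
                        waveform_spec(duration = 20, fs = 500,
                                      mains_amp = 0.05, seed = 2))
  expect_equal(estimate_heart_rate(sw$waveform), 60, tolerance = 2 / 60)

  expect_error(estimate_heart_rate(ppg_waveform(rep(1, 2000), 250)),
               "noise floor")
  expect_error(estimate_heart_rate(ppg_waveform(sin(1:200), 100)), "5 s")
})

test_that("the adaptive cutoff rule tracks heart rate within the design band", {
  s60 <- adaptive_filter_spec(60)
  expect_equal(c(s60$f_lo, s60$f_hi), c(0.5, 8))
  expect_identical(s60$order, 4L)
  s30 <- adaptive_filter_spec(30)
  expect_equal(s30$f_lo, 0.25)   # 0.5 * 0.5 Hz, inside [0.2, 0.8]
  expect_equal(s30$f_hi, 5)      # clipped up to the 5 Hz floor
  s110 <- adaptive_filter_spec(110)
  expect_equal(s110$f_hi, 10)    # ceiling of the chain's design band
  expect_equal(s110$f_lo, 0.8)   # 0.9167 clipped down
  expect_error(adaptive_filter_spec(200), "30, 180")
})

test_that("the band-pass meets its frequency-response contract", {
  fs <- 500
  spec <- filter_spec(0.5, 8, order = 4L)
  ba <- avfppg:::butter_bandpass(4, 0.5, 8, fs)
  # ~3 dB at the band edges (single pass), within 1 dB
  edge_db <- 20 * log10(Mod(filter_response(ba$b, ba$a, c(0.5, 8), fs)))
  expect_true(all(abs(edge_db - (-3.01)) < 1))
  # >= 20 dB down at both mains frequencies
  mains_db <- 20 * log10(Mod(filter_response(ba$b, ba$a, c(50, 60), fs)))
  expect_true(all(mains_db < -20))
  # passband essentially flat mid-band
  mid <- Mod(filter_response(ba$b, ba$a, c(1.5, 2, 3), fs))
  expect_true(all(abs(mid - 1) < 0.02))

  t <- seq(0, 10, by = 1 / fs)
  tone50 <- ppg_waveform(sin(2 * pi * 50 * t), fs)
  out50 <- apply_bandpass(tone50, spec)
  expect_lt(sqrt(mean(out50$samples^2)), 0.1 * sqrt(mean(tone50$samples^2)))

  dc <- ppg_waveform(rep(2.2, length(t)), fs)
  expect_lt(sqrt(mean(apply_bandpass(dc, spec)$samples^2)), 1e-3 * 2.2)

  tone1 <- ppg_waveform(sin(2 * pi * 1 * t), fs)
  out1 <- apply_bandpass(tone1, spec)
  mid_half <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- (max(out1$samples[mid_half]) - min(out1$samples[mid_half])) / 2
  expect_equal(amp, 1, tolerance = 0.05)

  expect_error(apply_bandpass(tone1, filter_spec(0.5, 300)), "Nyquist")
})

test_that("DC extraction averages out one full beat", {
  fs <- 200
  t <- seq(0, 15, by = 1 / fs)
  w_const <- ppg_waveform(rep(3.3, length(t)), fs)
  expect_equal(extract_dc(w_const, 72), rep(3.3, length(t)), tolerance = 1e-12)

  w_sin <- ppg_waveform(1.5 + 0.05 * sin(2 * pi * 1.2 * t), fs)
  dc <- extract_dc(w_sin, 72)  # hr frequency = 1.2 Hz
  expect_equal(mean(abs(dc - 1.5)) / 1.5, 0, tolerance = 0.02)

  # removing the DC estimate leaves a near-zero-mean residual
  resid <- w_sin$samples - dc
  expect_lt(abs(mean(extract_dc(ppg_waveform(resid + 1, fs), 72) - 1)), 0.002)

  expect_error(extract_dc(ppg_waveform(c(1, 2, 3), 10), 30), "window")
})

test_that("beat segmentation finds equal pulses and flags artifacts", {
  fs <- 250; period <- 1; n_pulses <- 8
  t <- seq(-0.5, n_pulses + 0.5, by = 1 / fs)
  x <- rep(0, length(t))
  for (k in -1:n_pulses) {
    u <- t - k
    sel <- u >= 0 & u < 1
    x[sel] <- x[sel] + avfppg:::.beat_template(u[sel])
  }
  ac <- ppg_waveform(x - mean(x), fs)
  beats <- segment_beats(ac, 60, dc = rep(1, length(t)))
  expect_true(nrow(beats) %in% c(n_pulses - 1, n_pulses))
  intervals <- beats$end - beats$start
  expect_true(all(abs(intervals - fs * period) <= 1))

  # one beat scaled 5x in amplitude is flagged artifact
  x_spike <- x
  sel <- t >= 3 & t < 4
  x_spike[sel] <- 5 * x_spike[sel]
  beats_sp <- segment_beats(ppg_waveform(x_spike - mean(x_spike), fs), 60,
                            dc = rep(1, length(t)))
  spiked <- which(beats_sp$start >= 3 * fs - 10 & beats_sp$end <= 4.6 * fs)
  expect_true(length(spiked) >= 1 && !any(beats_sp$valid[spiked]))

  expect_error(segment_beats(ppg_waveform(rep(1, 1000), fs), 60),
               "insufficient")
})

test_that("PI extrema are ratio-based and scale invariant", {
  fs <- 250
  # programmed per-beat PIs via the generator, zero corruption
  sw <- sample_waveform(list(pi_max = 0.020, pi_min = 0.010, hr = 60),
                        waveform_spec(duration = 20, fs = fs, mains_amp = 0,
                                      noise_sd = 0, drift_amp = 0, seed = 5))
  f <- extract_features_from_waveform(sw$waveform)
  expect_equal(f$pi_max, 0.020, tolerance = 0.05)
  expect_equal(f$pi_min, 0.010, tolerance = 0.05)

  # global scaling (and hence added pure gain) leaves PI unchanged
  w_scaled <- ppg_waveform(sw$waveform$samples * 7.3, fs)
  fs2 <- extract_features_from_waveform(w_scaled)
  expect_equal(fs2$pi_max, f$pi_max, tolerance = 1e-9)
  expect_equal(fs2$pi_min, f$pi_min, tolerance = 1e-9)

  # identical beats -> PI_max == PI_min (up to numerical wiggle)
  sw_c <- sample_waveform(list(pi_max = 0.015, pi_min = 0.015, hr = 72),
                          waveform_spec(duration = 20, fs = fs, mains_amp = 0,
                                        noise_sd = 0, drift_amp = 0, seed = 6))
  fc <- extract_features_from_waveform(sw_c$waveform)
  expect_equal(fc$pi_max / fc$pi_min, 1, tolerance = 0.01)
})

test_that("the PGA/ADC stage fills the range and stays within 1 LSB", {
  fs <- 100
  ramp <- ppg_waveform(seq(0, 1, length.out = 500), fs)
  adc <- simulate_pga_adc(ramp, bits = 12, vref = 3.3)
  expect_gte(max(adc$codes) - min(adc$codes), floor(0.9 * (2^12 - 1)))
  # quantization error bounded by 1 LSB
  v_exact <- adc$gain * ramp$samples + adc$offset
  expect_lte(max(abs(adc$waveform$samples - v_exact)), 3.3 / 2^12)
  expect_lte(sqrt(mean((adc$waveform$samples - v_exact)^2)), 3.3 / 2^12)

  # PI before vs after 16-bit conversion differs < 1%
  sw <- sample_waveform(list(pi_max = 0.02, pi_min = 0.014, hr = 72),
                        waveform_spec(duration = 20, fs = 250, seed = 8))
  before <- extract_features_from_waveform(sw$waveform)
  after <- extract_features_from_waveform(
    adc_invert(simulate_pga_adc(sw$waveform, bits = 16L)))
  expect_equal(after$pi_max / before$pi_max, 1, tolerance = 0.01)
  expect_equal(after$pi_min / before$pi_min, 1, tolerance = 0.01)

  expect_error(simulate_pga_adc(ppg_waveform(rep(1, 10), fs)), "zero-span")
  expect_error(simulate_pga_adc(ramp, bits = 30), "bits")
})
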