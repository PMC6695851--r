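# Shared fixtures built in code.

fixture_cal <- function(...) calibration_constants(...)

# the regression-fixture vessel: d0 = 0.5 cm, h = 0.05 cm, E = 4e6 dyn/cm^2,
# sigma 0.49, heart rate 72 bpm
fixture_vessel <- function() {
  vessel_state(D = 0.6, d = 0.5, d0 = 0.5, h1 = 0.05, h2 = 0,
               E = 4e6, sigma_p = 0.49, d_max = 0.52, d_min = 0.48)
}

fixture_hemo <- function() hemo_state(sbp = 120, dbp = 80, hr_bpm = 72)

# exhaustive kNN reference: plain distance sort + majority vote with the
# same tie-break contract, written independently of knn_classify
oracle_knn <- function(train_x, train_y, test_pt, k) {
  d <- apply(train_x, 1, function(r) sqrt(sum((r - test_pt)^2)))
  nb <- order(d)[seq_len(k)]
  y <- ifelse(tolower(train_y) == "positive", 1L, -1L)
  vp <- sum(y[nb] == 1); vn <- k - vp
  if (vp > vn) return("positive")
  if (vn > vp) return("negative")
  dp <- sum(d[nb][y[nb] == 1]); dn <- sum(d[nb][y[nb] == -1])
  if (dp < dn) "positive" else if (dn < dp) "negative" else "positive"
}

# run the full readout chain on a synthesized waveform
extract_features_from_waveform <- function(w) {
  hr <- estimate_heart_rate(w)
  ac <- apply_bandpass(w, adaptive_filter_spec(hr), equalize_hz = hr / 60)
  dc <- extract_dc(w, hr)
  ext <- compute_pi_extrema(segment_beats(ac, hr, dc))
  list(hr = hr, pi_max = ext$pi_max, pi_min = ext$pi_min)
}
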