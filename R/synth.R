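#' Specification of a synthetic hemodialysis cohort
#'
#' States the world the generator draws from: cohort size, the prevalence
#' of the clinically "positive" classes (stenosis below the 30% risk
#' threshold; flow above the 600 mL/min adequacy threshold), physiological
#' parameter ranges, and the relative measurement-noise level. Wall
#' mechanics (`E`, `sigma_p`, `h1`) and the optical calibration are taken
#' from a [calibration_constants()] object so that, at zero noise, the
#' feature inversion recovers each subject's latent state exactly.
#'
#' @param n_subjects cohort size
#' @param prev_dos_pos prevalence of the stenosis-negative-for-disease
#'   ("DOS-positive", DOS < 30%) class; default 45/74
#' @param prev_bfv_pos prevalence of the adequate-flow ("BFV-positive",
#'   BFV > 600 mL/min) class; default 61/79
#' @param D_range normal lumen diameter range, cm
#' @param dos_neg_range,dos_pos_range latent stenosis ranges (percent) for
#'   the healthy and diseased mixture components; the default gap around
#'   the 30% threshold controls separability
#' @param sbp_range,dbp_range pressure ranges, mmHg
#' @param spo2_range oxygen saturation range (fraction)
#' @param hr_range heart-rate range, bpm
#' @param noise_sd relative (multiplicative Gaussian) measurement noise on
#'   the features; default 0.02
#' @param seed integer seed (mandatory)
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 74,
                        prev_dos_pos = 45 / 74,
                        prev_bfv_pos = 61 / 79,
                        D_range = c(0.4, 0.8),
                        dos_pos_range = c(0, 25),
                        dos_neg_range = c(35, 80),
                        sbp_range = c(100, 160),
                        dbp_range = c(60, 95),
                        spo2_range = c(0.90, 0.99),
                        hr_range = c(50, 110),
                        noise_sd = 0.02,
                        seed) {
  if (missing(seed)) stop_domain("a seed is mandatory")
  if (n_subjects < 1) stop_domain("n_subjects must be >= 1")
  for (p in c(prev_dos_pos, prev_bfv_pos))  # NA = class left to physiology
    if (!is.na(p) && (p <= 0 || p >= 1))
      stop_domain("prevalences must lie in (0, 1)")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 prev_dos_pos = prev_dos_pos, prev_bfv_pos = prev_bfv_pos,
                 D_range = D_range, dos_pos_range = dos_pos_range,
                 dos_neg_range = dos_neg_range, sbp_range = sbp_range,
                 dbp_range = dbp_range, spo2_range = spo2_range,
                 hr_range = hr_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# forward model for one latent subject: geometry -> pulsatile diameters ->
# perfusion indices and average flow
.forward_subject <- function(D, dos, sbp, dbp, spo2, hr, cal) {
  d <- D * sqrt(1 - dos / 100)      # invert the area-ratio definition
  h <- cal$h1 + (D - d) / 2         # hyperplasia fills the lost lumen
  hemo <- hemo_state(sbp, dbp, hr)
  # pulsatile diameters consistent with the compliance relation, centred on d
  dp_cgs <- (sbp - dbp) * MMHG_TO_CGS
  delta2 <- (1 - cal$sigma_p^2) * pi * d^3 / (cal$E * h) * dp_cgs  # dmax^2-dmin^2
  half <- delta2 / (4 * d)                                          # (dmax-dmin)/2
  d_max <- d + half; d_min <- d - half
  if (d_min <= 0) return(NULL)
  oc <- optical_constants(eps_HbO = cal$eps_HbO, eps_Hb = cal$eps_Hb)
  pi_max <- pi_from_path(d_max / cal$kappa, spo2, oc)
  pi_min <- pi_from_path(d_min / cal$kappa, spo2, oc)
  vessel <- vessel_state(D = max(D, d_max), d = d, d0 = d, h1 = cal$h1,
                         h2 = h - cal$h1, E = cal$E, sigma_p = cal$sigma_p,
                         d_max = d_max, d_min = d_min)
  q <- average_bfv(vessel, hemo,
                   blood_properties(eta = cal$eta, rho = cal$rho, spo2 = spo2),
                   poiseuille_pi = cal$poiseuille_pi)
  list(d = d, h = h, d_max = d_max, d_min = d_min,
       pi_max = pi_max, pi_min = pi_min, dos = dos, q_avg = q,
       spo2 = spo2, vessel = vessel, hemo = hemo)
}

#' Draw a synthetic labeled cohort
#'
#' Each subject receives a latent vessel state drawn from the spec's
#' ranges: the stenosis class is drawn at the stated prevalence and the
#' continuous parameters are re-drawn (bounded retries) until the flow
#' class also matches its target prevalence draw. Features are the exact
#' forward-model perfusion indices and pressures with multiplicative
#' Gaussian noise; labels always reflect the noise-free latent state.
#'
#' @param spec [cohort_spec()]
#' @param cal [calibration_constants()] shared by generator and inversion
#' @param max_tries retry budget per subject before a generation error
#' @return data.frame of class `avf_cohort` with columns `subject_id`,
#'   `pi_max`, `pi_min`, `spo2`, `sbp`, `dbp`, `hr`, `dos_pct`,
#'   `bfv_ml_min`, `dos_label`, `bfv_label`; latent states attached as
#'   attribute `"latent"`
#' @export
sample_cohort <- function(spec, cal = calibration_constants(),
                          max_tries = 500L) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(spec$seed)
  n <- spec$n_subjects
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  rows <- vector("list", n)
  latent <- vector("list", n)
  for (i in seq_len(n)) {
    dos_pos <- stats::runif(1) < spec$prev_dos_pos
    bfv_pos <- if (is.na(spec$prev_bfv_pos)) NA else
      stats::runif(1) < spec$prev_bfv_pos
    fw <- NULL
    for (try in seq_len(max_tries)) {
      dos <- if (dos_pos) runif1(spec$dos_pos_range) else runif1(spec$dos_neg_range)
      D <- runif1(spec$D_range)
      sbp <- runif1(spec$sbp_range)
      dbp <- runif1(spec$dbp_range)
      if (sbp - dbp < 20) next
      spo2 <- runif1(spec$spo2_range)
      hr <- runif1(spec$hr_range)
      cand <- .forward_subject(D, dos, sbp, dbp, spo2, hr, cal)
      if (is.null(cand)) next
      if (is.na(bfv_pos) || (cand$q_avg > 600) == bfv_pos) { fw <- cand; break }
    }
    if (is.null(fw))
      stop_domain("generation error: could not realize the requested class ",
                  "combination within ", max_tries, " tries (subject ", i, ")")
    noise <- function(v) v * exp(stats::rnorm(1, 0, spec$noise_sd))
    pi_max_n <- noise(fw$pi_max); pi_min_n <- noise(fw$pi_min)
    if (pi_min_n > pi_max_n) { tmp <- pi_max_n; pi_max_n <- pi_min_n; pi_min_n <- tmp }
    sbp_n <- noise(fw$hemo$sbp); dbp_n <- noise(fw$hemo$dbp)
    if (sbp_n - dbp_n < 1) { sbp_n <- dbp_n + 1 }
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i),
      pi_max = pi_max_n, pi_min = pi_min_n,
      spo2 = min(noise(fw$spo2), 1),
      sbp = sbp_n, dbp = dbp_n, hr = noise(fw$hemo$hr_bpm),
      dos_pct = fw$dos, bfv_ml_min = fw$q_avg,
      dos_label = if (fw$dos < 30) "positive" else "negative",
      bfv_label = if (fw$q_avg > 600) "positive" else "negative",
      stringsAsFactors = FALSE)
    latent[[i]] <- fw
  }
  out <- do.call(rbind, rows)
  attr(out, "latent") <- latent
  class(out) <- c("avf_cohort", "data.frame")
  out
}

#' Specification of a synthetic raw PPG waveform
#'
#' The stated world mirrors what the sensor sees: a dominant DC floor
#' (>90% of the signal), a small pulsatile component, mains pickup, slow
#' baseline drift and white noise.
#'
#' @param duration record length, s
#' @param fs sampling rate, Hz (default 500)
#' @param dc_level DC floor (arbitrary units)
#' @param ac_fraction hard cap on AC/DC (must stay below 0.1)
#' @param mains_freq 50 or 60 Hz
#' @param mains_amp mains amplitude relative to DC
#' @param drift_amp,drift_period baseline drift relative amplitude and
#'   period (s)
#' @param noise_sd white-noise SD relative to DC
#' @param seed integer seed (mandatory)
#' @return object of class `waveform_spec`
#' @export
waveform_spec <- function(duration = 20, fs = 500, dc_level = 1,
                          ac_fraction = 0.05, mains_freq = 60,
                          mains_amp = 0.002, drift_amp = 0.01,
                          drift_period = 10, noise_sd = 5e-4, seed) {
  if (missing(seed)) stop_domain("a seed is mandatory")
  if (ac_fraction >= 0.1)
    stop_domain("ac_fraction must stay below 0.1 (the AC component is small)")
  if (!mains_freq %in% c(50, 60)) stop_domain("mains_freq must be 50 or 60")
  if (fs <= 2 * mains_freq) stop_domain("fs must exceed twice the mains frequency")
  structure(list(duration = duration, fs = fs, dc_level = dc_level,
                 ac_fraction = ac_fraction, mains_freq = mains_freq,
                 mains_amp = mains_amp, drift_amp = drift_amp,
                 drift_period = drift_period, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "waveform_spec")
}

# two-bump beat template on phase u in [0,1): systolic peak plus a
# dicrotic-notch-like secondary wave; smooth enough that its energy sits
# well inside the readout passband
.beat_template <- function(u) {
  exp(-0.5 * ((u - 0.30) / 0.10)^2) + 0.35 * exp(-0.5 * ((u - 0.65) / 0.18)^2)
}

#' Synthesize a raw PPG waveform for one subject
#'
#' A pulse train at the subject's heart rate whose per-beat AC amplitude is
#' scaled so AC/DC tracks the subject's perfusion-index trajectory (a
#' triangular sweep touching both `pi_min` and `pi_max`), on top of the DC
#' floor, mains pickup, slow drift, and white noise.
#'
#' @param subject list or one-row data.frame with `pi_max`, `pi_min`, `hr`
#' @param wspec [waveform_spec()]
#' @return list: `waveform` ([ppg_waveform()]), `pi_per_beat`, `hr_bpm`,
#'   `beat_starts` (s)
#' @export
sample_waveform <- function(subject, wspec) {
  stopifnot(inherits(wspec, "waveform_spec"))
  pi_max <- subject$pi_max; pi_min <- subject$pi_min; hr <- subject$hr
  if (pi_max >= wspec$ac_fraction)
    stop_domain("subject PI exceeds the spec's AC fraction cap")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(wspec$seed)
  fs <- wspec$fs
  t <- seq(0, wspec$duration, by = 1 / fs)
  period <- 60 / hr
  n_beats <- floor(wspec$duration / period)
  if (n_beats < 4) stop_domain("record too short for 4 beats at this heart rate")
  # respiratory-style PI modulation (8-beat cycle) touching both extremes
  # repeatedly in the record interior
  pis <- pi_min + (pi_max - pi_min) *
    (0.5 + 0.5 * cos(2 * pi * (seq_len(n_beats) - 3) / 8))
  uu <- seq(0, 1, length.out = 1000)
  g <- .beat_template(uu)
  tmpl_ptp <- max(g) - min(g)
  tmpl_mean <- mean(g)
  x <- rep(wspec$dc_level, length(t))
  beat_starts <- (seq_len(n_beats) - 1) * period
  for (k in seq_len(n_beats)) {
    u <- (t - beat_starts[k]) / period
    in_beat <- u >= 0 & u < 1
    # AC/DC must equal the programmed PI against the *measured* baseline,
    # which includes the pulse-train mean
    amp <- pis[k] * wspec$dc_level / (tmpl_ptp - pis[k] * tmpl_mean)
    x[in_beat] <- x[in_beat] + amp * .beat_template(u[in_beat])
  }
  x <- x +
    wspec$mains_amp * wspec$dc_level * sin(2 * pi * wspec$mains_freq * t) +
    wspec$drift_amp * wspec$dc_level * sin(2 * pi * t / wspec$drift_period) +
    stats::rnorm(length(t), 0, wspec$noise_sd * wspec$dc_level)
  list(waveform = ppg_waveform(x, fs, 0),
       pi_per_beat = pis, hr_bpm = hr, beat_starts = beat_starts)
}
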