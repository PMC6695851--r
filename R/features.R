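#' Classifier feature vector
#'
#' The six measurable inputs of the screening method: the maximum and
#' minimum per-beat perfusion indices, oxygen saturation, systolic and
#' diastolic pressure, and heart rate. Heart rate is only consumed by the
#' blood-flow task.
#'
#' @param pi_max,pi_min per-beat perfusion-index extremes,
#'   `pi_max >= pi_min > 0`
#' @param spo2 oxygen saturation fraction in \[0, 1\]
#' @param sbp,dbp pressures in mmHg, `sbp > dbp`
#' @param hr heart rate in bpm (may be `NA` for the stenosis task)
#' @return an object of class `feature_vector`
#' @export
feature_vector <- function(pi_max, pi_min, spo2, sbp, dbp, hr = NA_real_) {
  check_num(pi_max, "pi_max", positive = TRUE)
  check_num(pi_min, "pi_min", positive = TRUE)
  if (pi_max < pi_min) stop_domain("pi_max must be >= pi_min")
  check_num(spo2, "spo2")
  if (spo2 < 0 || spo2 > 1) stop_domain("spo2 must lie in [0, 1]")
  check_num(sbp, "sbp", positive = TRUE)
  check_num(dbp, "dbp", positive = TRUE)
  if (sbp <= dbp) stop_domain("sbp must exceed dbp")
  structure(list(pi_max = pi_max, pi_min = pi_min, spo2 = spo2,
                 sbp = sbp, dbp = dbp, hr = hr),
            class = "feature_vector")
}

# Shared first half of the feature inversion: PI extremes -> pulsatile
# diameters -> representative diameter -> wall thickness.
.features_to_vessel <- function(fv, cal) {
  stopifnot(inherits(fv, "feature_vector"),
            inherits(cal, "calibration_constants"))
  if (fv$pi_max <= fv$pi_min)
    stop_domain("pi_max must exceed pi_min (zero pulsatility is unobservable)")
  oc <- optical_constants(eps_HbO = cal$eps_HbO, eps_Hb = cal$eps_Hb)
  d_max <- cal$kappa * path_from_pi(fv$pi_max, fv$spo2, oc)
  d_min <- cal$kappa * path_from_pi(fv$pi_min, fv$spo2, oc)
  d0 <- (d_max + d_min) / 2
  hr <- if (is.finite(fv$hr)) fv$hr else 72
  hemo <- hemo_state(fv$sbp, fv$dbp, hr)
  probe <- vessel_state(D = d_max, d = d0, d0 = d0, h1 = cal$h1, h2 = 0,
                        E = cal$E, sigma_p = cal$sigma_p,
                        d_max = d_max, d_min = d_min)
  h <- vessel_thickness(probe, hemo)
  list(d0 = d0, d_max = d_max, d_min = d_min, h = h, hemo = hemo)
}

#' Degree of stenosis estimated from PPG features
#'
#' Deterministic inversion of the forward model: the perfusion-index
#' extremes are mapped back to pulsatile diameters through the
#' Beer-Lambert path (scaled by the calibration constant `kappa`), the
#' wall thickness follows from the compliance relation, and the stenosis
#' follows from the thickness identity. The estimate is invariant to the
#' joint rescaling (PI, kappa) -> (c PI, kappa / c).
#'
#' @param fv [feature_vector()]
#' @param cal [calibration_constants()]
#' @return estimated degree of stenosis, percent
#' @export
dos_from_features <- function(fv, cal = calibration_constants()) {
  inv <- .features_to_vessel(fv, cal)
  h <- max(inv$h, cal$h1)  # thickness can round below baseline numerically
  dos_from_thickness(inv$d0, h, cal$h1)
}

#' Blood-flow volume estimated from PPG features
#'
#' Inverts the feature map to a representative vessel (as in
#' [dos_from_features()]), builds the per-unit-length line parameters at
#' the subject's heart rate and divides the mean blood pressure by the
#' characteristic impedance.
#'
#' @inheritParams dos_from_features
#' @return estimated average flow, mL/min
#' @export
bfv_from_features <- function(fv, cal = calibration_constants()) {
  if (!is.finite(fv$hr)) stop_domain("heart rate is required for the flow task")
  inv <- .features_to_vessel(fv, cal)
  vessel <- vessel_state(D = inv$d_max, d = inv$d0, d0 = inv$d0,
                         h1 = cal$h1, h2 = max(inv$h - cal$h1, 0),
                         E = cal$E, sigma_p = cal$sigma_p,
                         d_max = inv$d_max, d_min = inv$d_min)
  average_bfv(vessel, inv$hemo,
              blood_properties(eta = cal$eta, rho = cal$rho,
                               spo2 = fv$spo2),
              poiseuille_pi = cal$poiseuille_pi)
}
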