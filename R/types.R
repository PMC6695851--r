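#' Physical and physiological parameter containers
#'
#' Lightweight validated S3 constructors for the quantities the forward model
#' needs: optical absorption constants, bulk blood properties, the geometric
#' and mechanical state of one fistula segment, and the pressure/heart-rate
#' context. All lengths are in cm, pressures in mmHg at the interface
#' (converted to CGS internally), elastic moduli in dyn/cm^2.
#'
#' @name avfppg-types
NULL

#' Pressure unit conversion factor: dyn/cm^2 per mmHg
#' @keywords internal
MMHG_TO_CGS <- 1333.22

stop_domain <- function(...) stop(..., call. = FALSE)

check_num <- function(x, name, positive = FALSE, nonneg = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop_domain(name, " must be a single numeric value")
  if (finite && !is.finite(x)) stop_domain(name, " must be finite")
  if (positive && x <= 0) stop_domain(name, " must be > 0")
  if (nonneg && x < 0) stop_domain(name, " must be >= 0")
  invisible(x)
}

#' Optical constants for the two-chromophore Beer-Lambert model
#'
#' @param eps_HbO molar absorption coefficient of oxy-hemoglobin
#'   (per cm, concentration lumped)
#' @param eps_Hb same for deoxy-hemoglobin
#' @param tissue_exponent lumped tissue attenuation exponent
#'   \eqn{\epsilon_t c_t s_t} (dimensionless)
#' @param I0 incident light intensity (arbitrary units)
#' @return an object of class `optical_constants`
#' @export
optical_constants <- function(eps_HbO = 1.2, eps_Hb = 0.8,
                              tissue_exponent = 0.5, I0 = 1) {
  check_num(eps_HbO, "eps_HbO", positive = TRUE)
  check_num(eps_Hb, "eps_Hb", positive = TRUE)
  check_num(tissue_exponent, "tissue_exponent", nonneg = TRUE)
  check_num(I0, "I0", positive = TRUE)
  if (eps_HbO == eps_Hb)
    stop_domain("eps_HbO and eps_Hb must differ")
  structure(list(eps_HbO = eps_HbO, eps_Hb = eps_Hb,
                 tissue_exponent = tissue_exponent, I0 = I0),
            class = "optical_constants")
}

#' Bulk blood properties
#'
#' Defaults are the conventional CGS values for whole blood: dynamic
#' viscosity 0.035 g/(cm s) and density 1.056 g/cm^3.
#'
#' @param eta dynamic viscosity, g/(cm s)
#' @param rho density, g/cm^3
#' @param spo2 oxygen saturation fraction in \[0, 1\]
#' @return an object of class `blood_properties`
#' @export
blood_properties <- function(eta = 0.035, rho = 1.056, spo2 = 0.97) {
  check_num(eta, "eta", positive = TRUE)
  check_num(rho, "rho", positive = TRUE)
  check_num(spo2, "spo2")
  if (spo2 < 0 || spo2 > 1) stop_domain("spo2 must lie in [0, 1]")
  structure(list(eta = eta, rho = rho, spo2 = spo2),
            class = "blood_properties")
}

#' Geometric and mechanical state of one fistula segment
#'
#' `D` is the normal (reference) lumen diameter, `d` the stenotic lumen,
#' `d0` the lumen diameter at the measuring spot, `h1` the baseline wall
#' thickness, `h2` the intimal-hyperplasia thickness (`h = h1 + h2`), `E`
#' the wall Young's modulus and `sigma_p` its Poisson ratio. `d_max`/`d_min`
#' are the pulsatile diameter extremes.
#'
#' @param D,d,d0,h1,h2,d_max,d_min lengths in cm
#' @param E Young's modulus, dyn/cm^2
#' @param sigma_p Poisson ratio, in \[0, 0.5)
#' @return an object of class `vessel_state` (with `h = h1 + h2`)
#' @export
vessel_state <- function(D, d, d0 = d, h1 = 0.03, h2 = 0,
                         E = 1.5e7, sigma_p = 0.49,
                         d_max = NA_real_, d_min = NA_real_) {
  check_num(D, "D", positive = TRUE)
  check_num(d, "d", positive = TRUE)
  check_num(d0, "d0", positive = TRUE)
  check_num(h1, "h1", nonneg = TRUE)
  check_num(h2, "h2", nonneg = TRUE)
  check_num(E, "E", positive = TRUE)
  check_num(sigma_p, "sigma_p", nonneg = TRUE)
  if (d > D) stop_domain("stenotic diameter d must not exceed D")
  if (sigma_p >= 0.5) stop_domain("sigma_p must be < 0.5")
  if (is.finite(d_max) && is.finite(d_min)) {
    if (d_min > d_max) stop_domain("d_min must not exceed d_max")
    if (d0 < d_min || d0 > d_max)
      stop_domain("d0 must lie in [d_min, d_max]")
  }
  structure(list(D = D, d = d, d0 = d0, h1 = h1, h2 = h2, h = h1 + h2,
                 E = E, sigma_p = sigma_p, d_max = d_max, d_min = d_min),
            class = "vessel_state")
}

#' Pressure and heart-rate context
#'
#' @param sbp,dbp systolic and diastolic pressure, mmHg
#' @param hr_bpm heart rate, beats/min; the angular frequency
#'   `omega = 2*pi*hr_bpm/60` is derived
#' @return an object of class `hemo_state`
#' @export
hemo_state <- function(sbp, dbp, hr_bpm) {
  check_num(sbp, "sbp", positive = TRUE)
  check_num(dbp, "dbp", positive = TRUE)
  check_num(hr_bpm, "hr_bpm", positive = TRUE)
  if (sbp <= dbp) stop_domain("sbp must exceed dbp")
  if (hr_bpm < 40 || hr_bpm > 200)
    stop_domain("hr_bpm outside the plausible range [40, 200]")
  structure(list(sbp = sbp, dbp = dbp, hr_bpm = hr_bpm,
                 omega = 2 * pi * hr_bpm / 60),
            class = "hemo_state")
}

#' Calibration constants for feature-to-physiology inversion
#'
#' Houses the quantities that turn measured perfusion indices back into
#' vessel geometry: the optical constants, the path-to-diameter
#' proportionality `kappa` (d = kappa * s_b), the assumed wall mechanics
#' (`E`, `sigma_p`, baseline thickness `h1`) and the Poiseuille-pi
#' bookkeeping switch.
#'
#' @param eps_HbO,eps_Hb absorption coefficients (per cm)
#' @param kappa path-to-diameter proportionality (dimensionless);
#'   default 30 makes a healthy 0.6 cm vessel read PI of about 0.02
#' @param E Young's modulus, dyn/cm^2
#' @param sigma_p Poisson ratio
#' @param h1 baseline wall thickness, cm
#' @param eta,rho blood viscosity and density (CGS)
#' @param poiseuille_pi include the pi of the standard Poiseuille
#'   per-unit-length resistance (default TRUE)
#' @return an object of class `calibration_constants`
#' @export
calibration_constants <- function(eps_HbO = 1.2, eps_Hb = 0.8, kappa = 30,
                                  E = 1.5e7, sigma_p = 0.49, h1 = 0.03,
                                  eta = 0.035, rho = 1.056,
                                  poiseuille_pi = TRUE) {
  check_num(kappa, "kappa", positive = TRUE)
  check_num(E, "E", positive = TRUE)
  check_num(sigma_p, "sigma_p", nonneg = TRUE)
  if (sigma_p >= 0.5) stop_domain("sigma_p must be < 0.5")
  check_num(h1, "h1", nonneg = TRUE)
  structure(list(eps_HbO = eps_HbO, eps_Hb = eps_Hb, kappa = kappa,
                 E = E, sigma_p = sigma_p, h1 = h1, eta = eta, rho = rho,
                 poiseuille_pi = isTRUE(poiseuille_pi)),
            class = "calibration_constants")
}
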