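#' Womersley number of pulsatile flow in a vessel
#'
#' \eqn{W = d_0 \sqrt{\omega \rho / (4 \eta)}}: the ratio of pulsatile
#' inertial to viscous forces. Dimensionless.
#'
#' @param d0 lumen diameter at the measuring spot, cm (> 0)
#' @param omega heart angular frequency, rad/s (> 0)
#' @param bp [blood_properties()]
#' @return Womersley number
#' @export
womersley <- function(d0, omega, bp = blood_properties()) {
  check_num(d0, "d0", positive = TRUE)
  check_num(omega, "omega", positive = TRUE)
  d0 * sqrt(omega * bp$rho / (4 * bp$eta))
}

#' Womersley correction factors for lumped resistance and inertance
#'
#' Affine fits \eqn{c_1 = 0.18 W + 0.45}, \eqn{c_2 = -0.018 W + 1.39}
#' correcting the Poiseuille resistance and plug-flow inertance for
#' oscillatory velocity profiles.
#'
#' @param W Womersley number (>= 0)
#' @return named list with `c1`, `c2`
#' @export
womersley_coeffs <- function(W) {
  check_num(W, "W", nonneg = TRUE)
  list(c1 = 0.18 * W + 0.45, c2 = -0.018 * W + 1.39)
}

#' Per-unit-length transmission-line parameters of a vessel segment
#'
#' Electrical analogy of the momentum and mass conservation equations:
#' \deqn{R = c_1 \frac{128\eta}{\pi d_0^4},\quad
#'       L = c_2 \frac{4\rho}{\pi d_0^2},\quad G = 0,\quad
#'       C = \frac{(1-\sigma^2)\pi d_0^3}{4 h E}.}
#' `G = 0` encodes the no-branch assumption. The pi in the Poiseuille
#' resistance can be dropped (`poiseuille_pi = FALSE`) to reproduce the
#' printed-formula bookkeeping exactly; the default keeps it.
#'
#' @param vessel [vessel_state()]; `d0`, `h`, `E`, `sigma_p` are used
#' @param hemo [hemo_state()]; supplies `omega`
#' @param bp [blood_properties()]
#' @param poiseuille_pi include pi in the denominator of R (default TRUE)
#' @return object of class `line_params` with fields `R`, `L`, `G`, `C`,
#'   `W`, `c1`, `c2`, `omega`
#' @export
line_params <- function(vessel, hemo, bp = blood_properties(),
                        poiseuille_pi = TRUE) {
  stopifnot(inherits(vessel, "vessel_state"), inherits(hemo, "hemo_state"))
  d0 <- vessel$d0; h <- vessel$h; E <- vessel$E; s <- vessel$sigma_p
  if (d0 <= 0 || h <= 0 || E <= 0)
    stop_domain("d0, h and E must all be > 0")
  W <- womersley(d0, hemo$omega, bp)
  cc <- womersley_coeffs(W)
  denomR <- if (isTRUE(poiseuille_pi)) pi * d0^4 else d0^4
  structure(list(
    R = cc$c1 * 128 * bp$eta / denomR,
    L = cc$c2 * 4 * bp$rho / (pi * d0^2),
    G = 0,
    C = (1 - s^2) * pi * d0^3 / (4 * h * E),
    W = W, c1 = cc$c1, c2 = cc$c2, omega = hemo$omega
  ), class = "line_params")
}

#' Attenuation and phase constants of the pressure/flow wave
#'
#' Principal square root of \eqn{(R + j\omega L)(G + j\omega C)}:
#' `alpha` (per cm) attenuates the forward-travelling wave, `beta`
#' (rad/cm) sets its phase velocity.
#'
#' @param lp [line_params()]
#' @param omega angular frequency, rad/s (defaults to `lp$omega`)
#' @return named list with `alpha`, `beta`, and the complex `gamma`
#' @export
propagation_constants <- function(lp, omega = lp$omega) {
  stopifnot(inherits(lp, "line_params"))
  gam <- sqrt((lp$R + 1i * omega * lp$L) * (lp$G + 1i * omega * lp$C))
  if (Re(gam) < 0) gam <- -gam  # principal branch: alpha >= 0
  list(alpha = Re(gam), beta = Im(gam), gamma = gam)
}

#' Characteristic impedance of the vessel transmission line
#'
#' \eqn{Z_0 = \sqrt{(R + j\omega L)/(G + j\omega C)}}, the ratio of the
#' forward pressure wave to the forward flow wave (principal branch).
#'
#' @inheritParams propagation_constants
#' @return complex impedance (CGS pressure / flow units)
#' @export
characteristic_impedance <- function(lp, omega = lp$omega) {
  stopifnot(inherits(lp, "line_params"))
  shunt <- lp$G + 1i * omega * lp$C
  if (Mod(shunt) == 0)
    stop_domain("G + j*omega*C is zero; characteristic impedance undefined")
  z0 <- sqrt((lp$R + 1i * omega * lp$L) / shunt)
  if (Re(z0) < 0) z0 <- -z0
  z0
}

#' Mean blood pressure from systolic and diastolic readings
#'
#' The standard time-weighted estimate MBP = SBP/3 + 2 DBP/3.
#'
#' @param sbp,dbp pressures in mmHg, `sbp > dbp`
#' @return MBP in mmHg
#' @export
mean_bp <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop_domain("sbp must exceed dbp")
  sbp / 3 + 2 * dbp / 3
}

#' Average blood-flow volume through the fistula
#'
#' The forward pressure wave is approximated by the mean blood pressure and
#' divided by the characteristic impedance:
#' \deqn{q_{avg} = \left| MBP \sqrt{(G + j\omega C)/(R + j\omega L)} \right|,}
#' with MBP converted to dyn/cm^2 and the flow reported in mL/min.
#'
#' @param vessel [vessel_state()]
#' @param hemo [hemo_state()]
#' @param bp [blood_properties()]
#' @param poiseuille_pi passed to [line_params()]
#' @return average flow, mL/min
#' @export
average_bfv <- function(vessel, hemo, bp = blood_properties(),
                        poiseuille_pi = TRUE) {
  lp <- line_params(vessel, hemo, bp, poiseuille_pi = poiseuille_pi)
  mbp_cgs <- mean_bp(hemo$sbp, hemo$dbp) * MMHG_TO_CGS
  z0 <- characteristic_impedance(lp)
  Mod(mbp_cgs / z0) * 60  # cm^3/s -> mL/min
}

#' Average vessel compliance from pulsatile areas and pulse pressure
#'
#' \eqn{C = (A_{max} - A_{min})/(SBP - DBP)} with pressures in dyn/cm^2.
#'
#' @param a_max,a_min maximal and minimal cross-sectional areas, cm^2
#' @param sbp,dbp pressures in mmHg
#' @return compliance, cm^2 per (dyn/cm^2)
#' @export
vessel_compliance <- function(a_max, a_min, sbp, dbp) {
  if (any(a_max < a_min)) stop_domain("a_max must be >= a_min")
  if (any(sbp <= dbp)) stop_domain("pulse pressure must be positive")
  (a_max - a_min) / ((sbp - dbp) * MMHG_TO_CGS)
}

#' Vessel wall thickness from pulsatile diameters and pulse pressure
#'
#' Equates the measured average compliance to the line compliance,
#' giving
#' \deqn{h = \frac{(1-\sigma^2)\pi d_0^3}{E}
#'   \frac{SBP - DBP}{d_{max}^2 - d_{min}^2}}
#' with pressures in dyn/cm^2. This printed form is taken as normative;
#' its constant factor differs from naively combining the line compliance
#' with circular areas (see the methods vignette).
#'
#' @param vessel [vessel_state()]; needs `d0`, `E`, `sigma_p`, `d_max`, `d_min`
#' @param hemo [hemo_state()]
#' @return wall thickness h, cm
#' @export
vessel_thickness <- function(vessel, hemo) {
  stopifnot(inherits(vessel, "vessel_state"), inherits(hemo, "hemo_state"))
  dmax <- vessel$d_max; dmin <- vessel$d_min
  if (!is.finite(dmax) || !is.finite(dmin))
    stop_domain("vessel must carry pulsatile diameters d_max, d_min")
  if (dmax <= dmin) stop_domain("d_max must exceed d_min")
  dp_cgs <- (hemo$sbp - hemo$dbp) * MMHG_TO_CGS
  (1 - vessel$sigma_p^2) * pi * vessel$d0^3 / vessel$E *
    dp_cgs / (dmax^2 - dmin^2)
}

#' Degree of stenosis from lumen diameters
#'
#' \eqn{DOS = (1 - d^2/D^2) \times 100\%}: the fractional loss of
#' cross-sectional area relative to the normal vessel.
#'
#' @param d stenotic lumen diameter, cm (0 < d <= D)
#' @param D normal lumen diameter, cm
#' @return DOS in percent, in \[0, 100)
#' @export
dos_from_geometry <- function(d, D) {
  if (any(d <= 0) || any(D <= 0)) stop_domain("diameters must be > 0")
  if (any(d > D)) stop_domain("d must not exceed D")
  100 * (1 - d^2 / D^2)
}

#' Degree of stenosis from wall thickness
#'
#' With hyperplasia thickness \eqn{h_2 = h - h_1} the normal diameter is
#' \eqn{D = d + 2h_2}, so
#' \eqn{DOS = (1 - d^2/(d + 2h - 2h_1)^2) \times 100\%}.
#'
#' @param d stenotic lumen diameter, cm (> 0)
#' @param h total wall thickness, cm (>= h1)
#' @param h1 baseline wall thickness, cm (>= 0)
#' @return DOS in percent
#' @export
dos_from_thickness <- function(d, h, h1) {
  if (any(d <= 0)) stop_domain("d must be > 0")
  if (any(h1 < 0) || any(h < h1)) stop_domain("need h >= h1 >= 0")
  dos_from_geometry(d, d + 2 * (h - h1))
}
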