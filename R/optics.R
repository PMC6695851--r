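#' Received light intensity under the two-layer Beer-Lambert model
#'
#' The photodiode sees the incident intensity attenuated by a stationary
#' tissue layer and by the pulsatile blood column:
#' \deqn{I_r = I_0 e^{-\epsilon_t c_t s_t} e^{-\epsilon_b c_b s_b}.}
#' Both exponents attenuate (absorption cannot amplify).
#'
#' @param oc [optical_constants()]
#' @param eps_b_c_b effective blood absorption per unit path (per cm)
#' @param s_b blood light-path length, cm (>= 0)
#' @return received intensity, same units as `oc$I0`
#' @export
received_intensity <- function(oc, eps_b_c_b, s_b) {
  stopifnot(inherits(oc, "optical_constants"))
  check_num(eps_b_c_b, "eps_b_c_b", nonneg = TRUE)
  check_num(s_b, "s_b")
  if (s_b < 0) stop_domain("path length s_b must be >= 0")
  oc$I0 * exp(-oc$tissue_exponent) * exp(-eps_b_c_b * s_b)
}

#' Effective blood absorption at a given oxygen saturation
#'
#' Linear two-chromophore mixture:
#' \eqn{\epsilon_b c_b = SpO_2\,\epsilon_{HbO} + (1 - SpO_2)\,\epsilon_{Hb}}.
#'
#' @param spo2 oxygen saturation fraction in \[0, 1\]
#' @param oc [optical_constants()] (only `eps_HbO`, `eps_Hb` used)
#' @return scalar absorption per unit path
#' @export
effective_absorption <- function(spo2, oc) {
  check_num(spo2, "spo2")
  if (spo2 < 0 || spo2 > 1) stop_domain("spo2 must lie in [0, 1]")
  spo2 * oc$eps_HbO + (1 - spo2) * oc$eps_Hb
}

#' Perfusion index from blood path length, and its inverse
#'
#' The perfusion index is the AC/DC ratio of the PPG signal; to first order
#' it is the blood path length scaled by the effective absorption:
#' \eqn{PI = s_b [SpO_2 \epsilon_{HbO} + (1-SpO_2)\epsilon_{Hb}]}.
#'
#' @param s_b blood light-path length, cm (>= 0)
#' @param spo2 oxygen saturation fraction
#' @param oc [optical_constants()]
#' @return `pi_from_path`: dimensionless PI; `path_from_pi`: s_b in cm
#' @export
pi_from_path <- function(s_b, spo2, oc) {
  if (any(s_b < 0)) stop_domain("path length s_b must be >= 0")
  s_b * effective_absorption(spo2, oc)
}

#' @rdname pi_from_path
#' @param pi_value perfusion index (>= 0)
#' @export
path_from_pi <- function(pi_value, spo2, oc) {
  if (any(pi_value < 0)) stop_domain("PI must be >= 0")
  eps <- effective_absorption(spo2, oc)
  if (eps == 0) stop_domain("effective absorption is zero; PI carries no path information")
  pi_value / eps
}
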