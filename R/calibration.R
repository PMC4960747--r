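#' Two-voltage B1 reference calibration
#'
#' The optimal transmitter reference voltage from two stimulated-echo
#' (STEAM) water acquisitions at 100 V and 200 V. A STEAM signal scales
#' as `sin^3(theta)`, so the amplitude ratio `S2/S1 = 8 cos^3(theta)`
#' identifies the flip angle `theta` reached at 100 V, and the voltage
#' producing 90 degrees is
#'
#' `B1 = 90 * 100 / ((180/pi) * acos(cbrt(S2 / (8 * S1))))`.
#'
#' @param s1 Water peak amplitude at 100 V; must be positive.
#' @param s2 Water peak amplitude at 200 V; must satisfy `s2 < 8 * s1`
#'   (the acos domain). Small negative values (noise at near-180-degree
#'   nulling) are clamped to zero with a warning.
#' @return The reference voltage in volts.
#' @export
#' @examples
#' reference_voltage(1, 0)  # 100 V: already 90 degrees at 100 V
#' reference_voltage(1, 1)  # 150 V
reference_voltage <- function(s1, s2) {
  if (length(s1) != 1 || length(s2) != 1)
    abort("`s1` and `s2` must be scalars.")
  if (s1 <= 0) abort("`s1` must be positive.")
  if (s2 < 0) {
    warn("`s2` below zero (noise); clamping to 0.")
    s2 <- 0
  }
  ratio <- s2 / (8 * s1)
  if (ratio >= 1)
    abort("`s2` must be below 8 * s1 (acos domain).")
  theta_deg <- (180 / pi) * acos(ratio^(1 / 3))
  90 * 100 / theta_deg
}
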