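#' Reduced units of the DMD system
#'
#' Lengths are in Angstrom, masses in amu, and energies in units of the
#' hydrogen-bond well depth \eqn{\epsilon_{HB}} = 12.47 kJ/mol.  The reduced
#' temperature is \eqn{T^* = k_B T / \epsilon_{HB}}.  The derived time unit is
#' \eqn{\tau = \sqrt{m_0 l_0^2 / \epsilon_{HB}}} with \eqn{m_0} = 1 amu and
#' \eqn{l_0} = 1 Angstrom.
#'
#' @return List with `epsilon_hb` (kJ/mol), `k_b` (kJ/mol/K) and `tau_ps`
#'   (the reduced time unit expressed in picoseconds, for reference only).
#' @export
reduced_units <- function() {
  eps <- 12.47          # kJ/mol
  kb <- 0.0083144621    # kJ/(mol K)
  # tau = sqrt(m l^2 / eps): 1 amu A^2 / (kJ/mol) = 1e-3 kg/mol * 1e-20 m^2 / (1e3 J/mol)
  tau_ps <- sqrt(1e-3 * 1e-20 / (eps * 1e3)) * 1e12
  list(epsilon_hb = eps, k_b = kb, tau_ps = tau_ps)
}

#' Convert Kelvin temperature to reduced temperature and back
#'
#' \eqn{T^* = k_B T / \epsilon_{HB}} with \eqn{\epsilon_{HB}} = 12.47 kJ/mol.
#' By this formula \eqn{T^* = 0.18} corresponds to about 270 K.  (Calibrations
#' of the four-bead model against experimental temperature scales place the
#' same state point nearer room temperature; such calibrations are external to
#' the formula, so both directions here use the definition only.)
#'
#' @param t_kelvin Temperature in Kelvin (> 0).
#' @param t_star Reduced temperature (> 0).
#' @return `reduced_temperature`: dimensionless \eqn{T^*};
#'   `kelvin_temperature`: Kelvin.
#' @examples
#' reduced_temperature(270)          # ~0.18
#' kelvin_temperature(0.18)          # ~270 K
#' @export
reduced_temperature <- function(t_kelvin) {
  stopifnot(is.numeric(t_kelvin))
  if (any(t_kelvin <= 0)) stop("temperature must be positive (Kelvin)")
  u <- reduced_units()
  u$k_b * t_kelvin / u$epsilon_hb
}

#' @rdname reduced_temperature
#' @export
kelvin_temperature <- function(t_star) {
  stopifnot(is.numeric(t_star))
  if (any(t_star <= 0)) stop("reduced temperature must be positive")
  u <- reduced_units()
  t_star * u$epsilon_hb / u$k_b
}
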