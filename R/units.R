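#' Coulomb coupling prefactor in angstrom-kelvin
#'
#' The constant \eqn{e^2 / (4 \pi \epsilon_0 k_B)} expressed in angstrom times
#' kelvin, used by [coupling_constant()]. Stored as a fixed named constant for
#' bit-stable reproducibility; a unit test verifies it against CODATA values of
#' the elementary charge, vacuum permittivity and Boltzmann constant.
#'
#' @format A length-one numeric.
#' @export
COULOMB_PREFACTOR_AA_K <- 167100.946898

#' Relative permittivity of water as a function of temperature
#'
#' Cubic polynomial approximation of the static relative permittivity
#' \eqn{\epsilon_r(T)} of liquid water:
#' \deqn{\epsilon_r(T) = 295.87696 + T(-1.229097 + T(0.0020952245 - 1.41\times 10^{-6} T))}
#' valid between the melting and boiling points at ambient pressure.
#'
#' @param T_kelvin temperature in kelvin (positive). A warning is emitted
#'   outside the calibrated range 273--373 K.
#' @return Dimensionless relative permittivity (about 78.3 at 298.15 K).
#' @examples
#' relative_permittivity(298.15)
#' @export
relative_permittivity <- function(T_kelvin) {
  if (!is.numeric(T_kelvin) || any(!is.finite(T_kelvin)) || any(T_kelvin <= 0))
    stop("T_kelvin must be positive and finite")
  if (any(T_kelvin < 273 | T_kelvin > 373))
    warning("relative_permittivity: temperature outside calibrated range [273, 373] K")
  295.87696 + T_kelvin * (-1.229097 +
    T_kelvin * (0.0020952245 - 0.00000141 * T_kelvin))
}

#' Dimensionless electrostatics coupling constant
#'
#' Strength of electrostatic interactions in reduced DPD units,
#' \deqn{\Gamma = \frac{e^2}{4\pi\epsilon_0 k_B \, \epsilon_r(T) \, R_{cutoff} \, T}}
#' with the physical DPD cutoff length \eqn{R_{cutoff}} in angstrom. The
#' numerator is the fixed prefactor [COULOMB_PREFACTOR_AA_K].
#'
#' @param T_kelvin temperature in kelvin (positive).
#' @param Rcutoff_angstrom physical length of one reduced DPD length unit, in
#'   angstrom (positive).
#' @return Dimensionless coupling constant \eqn{\Gamma}.
#' @examples
#' coupling_constant(300, 4.48) # about 1.6
#' @export
coupling_constant <- function(T_kelvin, Rcutoff_angstrom) {
  if (!is.numeric(T_kelvin) || any(T_kelvin <= 0))
    stop("T_kelvin must be positive")
  if (!is.numeric(Rcutoff_angstrom) || any(Rcutoff_angstrom <= 0))
    stop("Rcutoff_angstrom must be positive")
  COULOMB_PREFACTOR_AA_K /
    (relative_permittivity(T_kelvin) * Rcutoff_angstrom * T_kelvin)
}

#' Physical-unit mapping for reduced DPD quantities
#'
#' Maps reduced DPD units to physical units: length (angstrom per reduced
#' length unit), time (picoseconds per integration step) and the thermostat
#' target temperature in kelvin. Defaults correspond to one water molecule per
#' bead at number density 3 (4.48 angstrom per reduced unit) and 50 ps per
#' step.
#'
#' @param length_per_ru angstrom per reduced DPD length unit.
#' @param time_per_step_ps picoseconds of physical time per integration step.
#' @param temperature_K physical temperature represented by k_B T = 1.
#' @return An object of class `unit_mapping`.
#' @export
unit_mapping <- function(length_per_ru = 4.48, time_per_step_ps = 50,
                         temperature_K = 298.15) {
  for (v in c(length_per_ru, time_per_step_ps, temperature_K))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("unit_mapping fields must be single positive numbers")
  structure(list(length_per_ru = length_per_ru,
                 time_per_step_ps = time_per_step_ps,
                 temperature_K = temperature_K),
            class = "unit_mapping")
}

#' @export
print.unit_mapping <- function(x, ...) {
  cat(sprintf("unit_mapping: %g A/ru, %g ps/step, T = %g K\n",
              x$length_per_ru, x$time_per_step_ps, x$temperature_K))
  invisible(x)
}

#' Convert physical lengths to reduced DPD lengths
#'
#' @param um a [unit_mapping()].
#' @param length_angstrom length(s) in angstrom.
#' @return Length(s) in reduced DPD units.
#' @seealso [to_physical()]
#' @export
to_reduced <- function(um, length_angstrom) {
  stopifnot(inherits(um, "unit_mapping"))
  length_angstrom / um$length_per_ru
}

#' Convert reduced DPD lengths to physical lengths
#'
#' @param um a [unit_mapping()].
#' @param length_ru length(s) in reduced DPD units.
#' @return Length(s) in angstrom.
#' @export
to_physical <- function(um, length_ru) {
  stopifnot(inherits(um, "unit_mapping"))
  length_ru * um$length_per_ru
}

#' Convert step counts to microseconds
#'
#' @param um a [unit_mapping()].
#' @param steps integration step count(s).
#' @return Physical time in microseconds.
#' @export
steps_to_microseconds <- function(um, steps) {
  stopifnot(inherits(um, "unit_mapping"))
  steps * um$time_per_step_ps * 1e-6
}
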