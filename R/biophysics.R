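# Radiative and convective heat-transfer calculators used to interpret
# surface-minus-ambient temperature differences.

#' Stefan-Boltzmann constant, W m^-2 K^-4
#' @export
stefan_boltzmann <- 5.670374419e-8

#' Convert degrees Celsius to Kelvin
#'
#' @param c Temperature(s) in degC.
#' @return Temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(c) {
  stopifnot(is.numeric(c), all(is.finite(c)))
  c + 273.15
}

#' Forced convective heat flux
#'
#' `Q = h_c * A * delta_t`: bilinear in area and temperature difference,
#' with the sign following the temperature difference.
#'
#' @param h_c Surface heat transfer coefficient, W m^-2 K^-1.
#' @param area Exchange surface area, m^2; must be positive.
#' @param delta_t Surface-minus-environment temperature difference, K.
#' @return Heat flux Q, W.
#' @export
forced_convection <- function(h_c, area, delta_t) {
  stopifnot(is.numeric(h_c), is.numeric(area), is.numeric(delta_t))
  if (any(area <= 0)) stopf("surface area must be positive")
  h_c * area * delta_t
}

#' Surface heat transfer coefficient from wind speed and body dimension
#'
#' `h_c = c * V^k1 / D^k2`. The exponents bundle thermal conductivity,
#' capacity and expansion properties of the boundary layer and are
#' organism-specific inputs; the proportionality constant `c` absorbs the
#' unspecified scaling, so no biological defaults are asserted for `k1`,
#' `k2`.
#'
#' @param wind_speed Wind speed V, m s^-1; non-negative.
#' @param dimension Characteristic body dimension D, m; positive.
#' @param k1,k2 Dimensionless exponents.
#' @param c Proportionality constant (default 1).
#' @return h_c in the units implied by `c`.
#' @export
surface_heat_transfer_coefficient <- function(wind_speed, dimension, k1, k2,
                                              c = 1) {
  stopifnot(is.numeric(wind_speed), is.numeric(dimension),
            is_scalar_number(k1), is_scalar_number(k2), is_scalar_number(c))
  if (any(wind_speed < 0)) stopf("wind speed must be non-negative")
  if (any(dimension <= 0)) stopf("characteristic dimension must be positive")
  c * wind_speed^k1 / dimension^k2
}

#' Net long-wave radiation exchange
#'
#' `Q_n = A * emissivity * sigma * (T_o^4 - T_e^4)` with temperatures in
#' Kelvin (the fourth-power law is meaningless in Celsius; see
#' [celsius_to_kelvin()]). The default emissivity 0.93 matches the infrared
#' thermometer setting used for animal surface temperatures.
#'
#' @param area Radiating surface area, m^2; positive.
#' @param emissivity Surface emissivity in `[0, 1]`.
#' @param t_org Organism surface temperature, K; positive.
#' @param t_env Environment temperature, K; positive.
#' @return Net radiation Q_n, W (positive when the organism is warmer).
#' @export
net_radiation <- function(area, emissivity = 0.93, t_org, t_env) {
  stopifnot(is.numeric(area), is.numeric(emissivity),
            is.numeric(t_org), is.numeric(t_env))
  if (any(area <= 0)) stopf("surface area must be positive")
  if (any(emissivity < 0 | emissivity > 1)) stopf("emissivity must lie in [0, 1]")
  if (any(t_org <= 0) || any(t_env <= 0))
    stopf("temperatures must be in Kelvin (> 0); see celsius_to_kelvin()")
  area * emissivity * stefan_boltzmann * (t_org^4 - t_env^4)
}
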