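# Seawater dissolved-oxygen solubility and percent-air-saturation
# conversions.
#
# The solubility fit is the Garcia & Gordon (1992) re-fit of the
# Benson & Krause data, combined fit, volumetric (cm^3 dm^-3) variant,
# referenced to water-saturated air at 1 atm total pressure. The fitted
# value is converted to micromolar with the ideal molar volume of O2 at
# STP (22.3916 L mol^-1, i.e. 44.6596 umol per cm^3 O2).

# Garcia & Gordon (1992), Table 1, combined fit, cm^3 dm^-3.
.GG92_A <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
.GG92_B <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
.GG92_C0 <- -4.88682e-7
.UMOL_PER_CM3_O2 <- 44.6596

#' Oxygen conditions for solubility conversions
#'
#' Bundle of the physical conditions that fix the equilibrium dissolved
#' oxygen concentration of seawater in contact with water-saturated air.
#'
#' @param temperature_C Water temperature in degrees Celsius, in
#'   \eqn{[-2, 40]} (the fit's calibrated range).
#' @param salinity Practical salinity (dimensionless), in \eqn{[0, 42]}.
#' @param pressure_atm Total barometric pressure in atm. Only 1 atm moist
#'   air is supported; the argument documents the reference state.
#'
#' @return An object of class `oxygen_conditions`.
#' @examples
#' oxygen_conditions(26, 32)
#' @export
oxygen_conditions <- function(temperature_C, salinity, pressure_atm = 1) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(salinity), length(salinity) == 1L)
  if (!is.finite(temperature_C) || temperature_C < -2 || temperature_C > 40)
    stop("temperature_C must be in [-2, 40] degC, got ", temperature_C)
  if (!is.finite(salinity) || salinity < 0 || salinity > 42)
    stop("salinity must be in [0, 42], got ", salinity)
  if (!isTRUE(all.equal(pressure_atm, 1)))
    stop("only 1 atm moist air is supported")
  structure(
    list(temperature_C = temperature_C, salinity = salinity,
         pressure_atm = pressure_atm),
    class = "oxygen_conditions")
}

#' @export
print.oxygen_conditions <- function(x, ...) {
  cat(sprintf("oxygen_conditions: T = %g degC, S = %g, P = %g atm\n",
              x$temperature_C, x$salinity, x$pressure_atm))
  invisible(x)
}

#' Equilibrium dissolved O2 at 100% air saturation
#'
#' Dissolved oxygen concentration of seawater in equilibrium with
#' water-saturated air at 1 atm, in micromoles per litre. At the study
#' conditions of 26 degC and salinity 32 this is approximately 211 uM.
#'
#' @param conditions An [oxygen_conditions()] object.
#' @return Equilibrium concentration in umol per litre (uM).
#' @examples
#' o2_saturation_uM(oxygen_conditions(26, 32))
#' @export
o2_saturation_uM <- function(conditions) {
  stopifnot(inherits(conditions, "oxygen_conditions"))
  T <- conditions$temperature_C
  S <- conditions$salinity
  # scaled temperature of the fit
  ts <- log((298.15 - T) / (273.15 + T))
  ln_c <- sum(.GG92_A * ts^(0:5)) + S * sum(.GG92_B * ts^(0:3)) +
    .GG92_C0 * S^2
  exp(ln_c) * .UMOL_PER_CM3_O2
}

#' Convert between percent air saturation and micromolar O2
#'
#' Percent air saturation (%AS) expresses dissolved oxygen relative to
#' the equilibrium concentration returned by [o2_saturation_uM()]; the
#' conversion is linear in percent, so the two functions are exact
#' inverses.
#'
#' @param percent Percent air saturation (>= 0; values above 100 denote
#'   supersaturation and are allowed).
#' @param conc_uM Dissolved O2 in umol per litre (>= 0).
#' @param conditions An [oxygen_conditions()] object.
#' @return `percent_as_to_uM`: concentration in uM; `uM_to_percent_as`:
#'   percent air saturation.
#' @examples
#' cond <- oxygen_conditions(26, 32)
#' percent_as_to_uM(10, cond)     # ~21.1 uM
#' uM_to_percent_as(3.9, cond)    # ~1.86 %AS
#' @export
percent_as_to_uM <- function(percent, conditions) {
  stopifnot(is.numeric(percent))
  if (any(!is.finite(percent)) || any(percent < 0))
    stop("percent air saturation must be finite and >= 0")
  percent / 100 * o2_saturation_uM(conditions)
}

#' @rdname percent_as_to_uM
#' @export
uM_to_percent_as <- function(conc_uM, conditions) {
  stopifnot(is.numeric(conc_uM))
  if (any(!is.finite(conc_uM)) || any(conc_uM < 0))
    stop("O2 concentration must be finite and >= 0")
  conc_uM / o2_saturation_uM(conditions) * 100
}
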