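#' Convert Fraction Modern to Delta14C
#'
#' Applies the age correction between the 1950 reference and the sampling
#' year using the radiocarbon decay constant \eqn{\lambda = 1/8267}
#' yr\eqn{^{-1}}:
#' \deqn{\Delta^{14}C_{sample} = (F^{14}C \cdot e^{\lambda (1950 - t)} - 1)
#'   \times 1000.}
#' Fractional sampling years are accepted (sampling dates span mid-year).
#'
#' @param f14c Fraction Modern (dimensionless, > 0); the measured ratio
#'   normalized to \eqn{\delta^{13}}C = -25 permil relative to 0.95 x OX-I.
#' @param t sampling year (calendar, possibly fractional).
#'
#' @return \eqn{\Delta^{14}}C of the sample (permil).
#' @seealso \code{\link{delta14c_to_f14c}} for the inverse,
#'   \code{\link{background_correct}}.
#' @examples
#' f14c_to_delta14c(1, 1950)  # 0
#' f14c_to_delta14c(1, 2015)  # about -7.8
#' @export
f14c_to_delta14c <- function(f14c, t) {
  if (any(!is.finite(f14c)) || any(f14c <= 0))
    stop("f14c must be finite and > 0", call. = FALSE)
  if (any(!is.finite(t)))
    stop("t must be finite", call. = FALSE)
  (f14c * exp(LAMBDA_14C * (1950 - t)) - 1) * 1000
}

#' Convert Delta14C back to Fraction Modern
#'
#' Exact inverse of \code{\link{f14c_to_delta14c}}.
#'
#' @param delta14c \eqn{\Delta^{14}}C (permil, >= -1000).
#' @param t sampling year.
#' @return Fraction Modern.
#' @export
delta14c_to_f14c <- function(delta14c, t) {
  if (any(!is.finite(delta14c)) || any(delta14c <= -1000))
    stop("delta14c must be finite and > -1000 permil", call. = FALSE)
  (delta14c / 1000 + 1) * exp(LAMBDA_14C * (t - 1950))
}

#' Background-correct a Delta14C value
#'
#' Subtracts the atmospheric \eqn{\Delta^{14}}C in the year of sample
#' collection, so that samples collected in different years share a common
#' reference:
#' \eqn{\Delta^{14}C = \Delta^{14}C_{sample} - \Delta^{14}C_{atmosphere}(t)}.
#'
#' @param delta14c_sample sample \eqn{\Delta^{14}}C (permil), from
#'   \code{\link{f14c_to_delta14c}}.
#' @param curve an \code{\link[=atm_delta14c]{atmospheric curve}}.
#' @param t sampling year(s); must lie within the curve domain.
#'
#' @return Background-corrected \eqn{\Delta^{14}}C (permil).
#' @export
background_correct <- function(delta14c_sample, curve, t) {
  delta14c_sample - atm_delta14c(curve, t)
}

#' delta13C of soil inorganic carbon by mass balance
#'
#' Solves the total-carbon mass balance
#' \eqn{\delta^{13}C_{TC} w_{TC} = \delta^{13}C_{SOC} w_{SOC} +
#' \delta^{13}C_{SIC} w_{SIC}} for the carbonate signature. Because total C
#' (dry combustion) and SIC (ignition residue) are measured by different
#' methods, exact closure of \eqn{w_{TC} = w_{SOC} + w_{SIC}} is not
#' guaranteed: imbalance above \code{tol_warn} (relative) warns, above
#' \code{tol_error} it is an error.
#'
#' @param d13c_tc,d13c_soc \eqn{\delta^{13}}C of total C and SOC (permil
#'   VPDB).
#' @param w_tc,w_soc,w_sic carbon contents (mass-\% C) of total C, SOC and
#'   SIC.
#' @param tol_warn,tol_error relative mass-balance tolerances (defaults 0.10
#'   and 0.25).
#'
#' @return \eqn{\delta^{13}}C of SIC (permil VPDB).
#' @examples
#' delta13c_sic(-18, 2, -24, 1.5, 0.5)  # 0
#' @export
delta13c_sic <- function(d13c_tc, w_tc, d13c_soc, w_soc, w_sic,
                         tol_warn = 0.10, tol_error = 0.25) {
  if (any(c(w_tc, w_soc, w_sic) < 0, na.rm = TRUE))
    stop("carbon contents must be non-negative", call. = FALSE)
  if (any(w_sic == 0, na.rm = TRUE))
    stop("w_sic = 0: no carbonate; SIC signature undefined", call. = FALSE)
  imbalance <- abs(w_tc - (w_soc + w_sic)) / w_tc
  if (any(imbalance > tol_error, na.rm = TRUE))
    stop("carbon mass balance violated: w_tc differs from w_soc + w_sic by ",
         "more than ", round(100 * tol_error), "% (max ",
         round(100 * max(imbalance, na.rm = TRUE), 1), "%)", call. = FALSE)
  if (any(imbalance > tol_warn, na.rm = TRUE))
    warning("w_tc and w_soc + w_sic differ by more than ",
            round(100 * tol_warn), "% for some samples", call. = FALSE)
  (d13c_tc * w_tc - d13c_soc * w_soc) / w_sic
}

#' Soil respiration rate from headspace CO2 accumulation
#'
#' Converts the slope of headspace CO2 concentration over time to a
#' per-unit-soil-mass production rate via the ideal gas law:
#' \deqn{\mathrm{rate} = \frac{dC}{dt} \cdot
#'   \frac{P V M_{CO_2}}{R T m_{soil}}}
#' with \eqn{R} = 0.082057 L atm mol\eqn{^{-1}} K\eqn{^{-1}} and
#' \eqn{M_{CO_2}} = 44.01 g mol\eqn{^{-1}}. Defaults reflect the static
#' incubation setup (570 mL flask with ~30 g soil at 20 degC).
#'
#' @param co2_slope increase in headspace CO2 (ppm day^-1), >= 0.
#' @param headspace_pressure headspace pressure (atm).
#' @param headspace_volume headspace volume (L).
#' @param temperature incubation temperature (K).
#' @param soil_mass dry soil mass (g).
#'
#' @return Respiration rate (ug CO2 g soil^-1 day^-1).
#' @examples
#' respiration_rate(100, 1, 0.54, 293.15, 30)  # about 3.29
#' @export
respiration_rate <- function(co2_slope, headspace_pressure = 1,
                             headspace_volume = 0.54,
                             temperature = 293.15, soil_mass = 30) {
  if (any(co2_slope < 0, na.rm = TRUE))
    stop("co2_slope must be non-negative", call. = FALSE)
  phys <- c(headspace_pressure, headspace_volume, temperature, soil_mass)
  if (any(!is.finite(phys)) || any(phys <= 0))
    stop("pressure, volume, temperature and soil mass must be positive",
         call. = FALSE)
  # ppm day^-1 -> mol fraction day^-1 (1e-6) -> g CO2 day^-1 -> ug g^-1 day^-1
  # (1e6); the two factors cancel.
  co2_slope * headspace_pressure * headspace_volume * M_CO2 /
    (R_GAS * temperature * soil_mass)
}
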