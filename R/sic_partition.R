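#' delta13C of CO2 in isotopic equilibrium with soil carbonate
#'
#' CO2 equilibrated with calcite is depleted relative to the solid phase by
#' the calcite--CO2 fractionation, about 9.6 permil at the 20 degC incubation
#' temperature:
#' \eqn{\delta^{13}C\mbox{-}SIC_{equilibrium} = \delta^{13}C_{SIC} - 9.6}.
#'
#' @param d13c_sic measured \eqn{\delta^{13}}C of SIC (permil VPDB).
#' @param fractionation calcite--CO2 fractionation (permil); temperature
#'   dependence is not modelled.
#' @return \eqn{\delta^{13}}C of carbonate-equilibrated CO2 (permil).
#' @examples
#' sic_equilibrium_d13c(0)  # -9.6
#' @export
sic_equilibrium_d13c <- function(d13c_sic, fractionation = 9.6) {
  if (any(!is.finite(d13c_sic)))
    stop("d13c_sic must be finite", call. = FALSE)
  d13c_sic - fractionation
}

#' Carbonate share of respired CO2 from delta13C mass balance
#'
#' Two-endmember mixing between SOC-derived CO2 and carbonate-equilibrated
#' CO2:
#' \deqn{f_{SIC} = \frac{\delta^{13}C\mbox{-}CO_2 - \delta^{13}C_{SOC}}
#'   {\delta^{13}C\mbox{-}SIC_{equilibrium} - \delta^{13}C_{SOC}}, \qquad
#'   f_{SIC} + f_{SOC} = 1.}
#' Estimates pushed outside [0, 1] by measurement noise are clamped to the
#' boundary and flagged rather than erroring.
#'
#' @param d13c_co2 \eqn{\delta^{13}}C of respired CO2 (permil).
#' @param d13c_sic_eq carbonate-equilibrated endmember, from
#'   \code{\link{sic_equilibrium_d13c}} (permil).
#' @param d13c_soc SOC-derived CO2 endmember (permil).
#' @param separation_floor minimum endmember separation (permil) below which
#'   the partition is unidentifiable (error).
#'
#' @return A data frame with columns \code{f_sic}, \code{f_soc} (summing to
#'   1 exactly) and logical \code{clamped}.
#' @examples
#' f_sic_from_d13c(-20, -8, -24)  # f_sic = 0.25
#' @export
f_sic_from_d13c <- function(d13c_co2, d13c_sic_eq, d13c_soc,
                            separation_floor = 2) {
  sep <- abs(d13c_sic_eq - d13c_soc)
  if (any(sep < separation_floor, na.rm = TRUE))
    stop("unidentifiable partition: endmember delta13C separation below ",
         separation_floor, " permil", call. = FALSE)
  raw <- (d13c_co2 - d13c_soc) / (d13c_sic_eq - d13c_soc)
  clamped <- raw < 0 | raw > 1
  f_sic <- pmin(pmax(raw, 0), 1)
  data.frame(f_sic = f_sic, f_soc = 1 - f_sic, clamped = clamped)
}

#' Remove the carbonate contribution from respired Delta14C
#'
#' Inverts the \eqn{\Delta^{14}}C mixing between SOC- and carbonate-derived
#' CO2 to recover the SOC-derived signature:
#' \deqn{\Delta^{14}C\mbox{-}CO_{2,SOC} =
#'   \frac{\Delta^{14}C\mbox{-}CO_2 - f_{SIC} \,
#'   \Delta^{14}C\mbox{-}CO_{2,SIC}}{1 - f_{SIC}}.}
#'
#' @param delta14c_co2 measured \eqn{\Delta^{14}}C of total respired CO2
#'   (permil).
#' @param f_sic carbonate fraction of respired CO2, in [0, 1).
#' @param delta14c_co2_sic \eqn{\Delta^{14}}C of carbonate-derived CO2
#'   (permil); radiocarbon-dead parent material is -1000.
#'
#' @return \eqn{\Delta^{14}}C of SOC-derived CO2 (permil).
#' @examples
#' adjust_delta14c_for_sic(-100, 0.25, -600)  # +66.67
#' @export
adjust_delta14c_for_sic <- function(delta14c_co2, f_sic, delta14c_co2_sic) {
  if (any(f_sic < 0 | f_sic >= 1, na.rm = TRUE))
    stop("f_sic must be in [0, 1); f_sic = 1 means no SOC-derived CO2",
         call. = FALSE)
  (delta14c_co2 - f_sic * delta14c_co2_sic) / (1 - f_sic)
}

#' Screen a site's respired CO2 for carbonate contamination
#'
#' Applies the inclusion/exclusion rules, in order: SIC content below the
#' floor (default 0.1 mass-\%) means all respired CO2 is attributed to SOC
#' (\code{assumed_zero_sic}); a carbonate share above the exclusion cut
#' (default 15\%) drops the site (\code{excluded_high_fsic}); sites in a
#' configured excluded region are dropped (\code{excluded_region});
#' otherwise the site is retained with its original, unadjusted respired
#' \eqn{\Delta^{14}}C (\code{included_original}).
#'
#' @param sic_content SIC content (mass-\% C), >= 0.
#' @param f_sic estimated carbonate fraction of respired CO2 (ignored below
#'   the SIC floor; may be NA there).
#' @param region region label(s), or NA.
#' @param config an \code{\link{arid14c_config}}.
#'
#' @return Character vector of statuses, one of \code{assumed_zero_sic},
#'   \code{included_original}, \code{excluded_high_fsic},
#'   \code{excluded_region}.
#' @examples
#' screen_site(0.05, NA)         # assumed_zero_sic
#' screen_site(1.0, 0.20)        # excluded_high_fsic
#' screen_site(1.0, 0.10)        # included_original
#' @export
screen_site <- function(sic_content, f_sic, region = NA_character_,
                        config = arid14c_config()) {
  if (any(sic_content < 0, na.rm = TRUE))
    stop("sic_content must be non-negative", call. = FALSE)
  n <- max(length(sic_content), length(f_sic), length(region))
  sic_content <- rep_len(sic_content, n)
  f_sic <- rep_len(f_sic, n)
  region <- rep_len(region, n)
  floor_pct <- config$sic_content_floor * 100  # config floor is a mass fraction
  status <- rep("included_original", n)
  status[!is.na(f_sic) & f_sic > config$f_sic_exclusion] <-
    "excluded_high_fsic"
  status[!is.na(region) & region %in% config$excluded_regions &
           status == "included_original"] <- "excluded_region"
  status[sic_content < floor_pct] <- "assumed_zero_sic"
  status
}

#' Full carbonate partition of a site's respired CO2
#'
#' Runs the delta13C partition, the Delta14C adjustment and the screening
#' for one or more sites, returning one record per site. Sites below the SIC
#' floor get \code{f_sic = 0} by assumption; for all other sites the
#' partition is computed from the measured \eqn{\delta^{13}}C values. The
#' SOC-derived \eqn{\Delta^{14}}C (\code{delta14c_co2_soc}) is reported for
#' audit, but downstream analysis of included sites uses the original
#' respired \eqn{\Delta^{14}}C, mirroring the screening policy.
#'
#' @param d13c_co2 \eqn{\delta^{13}}C of respired CO2 (permil).
#' @param d13c_soc \eqn{\delta^{13}}C of SOC (permil).
#' @param d13c_sic \eqn{\delta^{13}}C of SIC (permil); may be NA below the
#'   SIC floor.
#' @param sic_content SIC content (mass-\% C).
#' @param delta14c_co2 \eqn{\Delta^{14}}C of respired CO2 (permil).
#' @param region region label(s).
#' @param delta14c_sic measured \eqn{\Delta^{14}}C of SIC (permil); when NA
#'   the configured carbonate endmember is used.
#' @param config an \code{\link{arid14c_config}}.
#'
#' @return A data frame with columns \code{d13c_sic_eq}, \code{f_sic},
#'   \code{f_soc}, \code{clamped}, \code{delta14c_co2_soc}, \code{status},
#'   \code{reason}.
#' @export
sic_partition <- function(d13c_co2, d13c_soc, d13c_sic, sic_content,
                          delta14c_co2, region = NA_character_,
                          delta14c_sic = NA_real_,
                          config = arid14c_config()) {
  n <- length(sic_content)
  d13c_co2 <- rep_len(d13c_co2, n); d13c_soc <- rep_len(d13c_soc, n)
  d13c_sic <- rep_len(d13c_sic, n); delta14c_co2 <- rep_len(delta14c_co2, n)
  region <- rep_len(region, n); delta14c_sic <- rep_len(delta14c_sic, n)

  floor_pct <- config$sic_content_floor * 100
  below <- sic_content < floor_pct

  d13c_sic_eq <- rep(NA_real_, n)
  f_sic <- rep(0, n)
  clamped <- rep(FALSE, n)
  above <- which(!below)
  if (length(above)) {
    d13c_sic_eq[above] <- sic_equilibrium_d13c(
      d13c_sic[above], config$calcite_co2_fractionation)
    part <- f_sic_from_d13c(d13c_co2[above], d13c_sic_eq[above],
                            d13c_soc[above], config$d13c_separation_floor)
    f_sic[above] <- part$f_sic
    clamped[above] <- part$clamped
  }

  sic_end <- ifelse(is.na(delta14c_sic), config$delta14c_sic_endmember,
                    delta14c_sic)
  delta14c_co2_soc <- ifelse(
    f_sic < 1,
    (delta14c_co2 - f_sic * sic_end) / (1 - f_sic),
    NA_real_)

  status <- screen_site(sic_content, f_sic, region, config)
  reason <- c(
    assumed_zero_sic = paste0("SIC content below ", floor_pct,
                              "%; all respired CO2 attributed to SOC"),
    included_original = "f_SIC within limits; original respired Delta14C used",
    excluded_high_fsic = paste0("f_SIC exceeds ",
                                100 * config$f_sic_exclusion, "%"),
    excluded_region = "region excluded from respiration analyses"
  )[status]
  data.frame(d13c_sic_eq = d13c_sic_eq, f_sic = f_sic, f_soc = 1 - f_sic,
             clamped = clamped, delta14c_co2_soc = delta14c_co2_soc,
             status = status, reason = unname(reason))
}
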