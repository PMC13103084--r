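#' Old-carbon fraction of respired CO2 by Delta14C mixing
#'
#' Two-endmember mixing of respired CO2 between an old and a young carbon
#' source:
#' \deqn{\Delta^{14}C_{CO_2} = \Delta^{14}C_{old} f_{old} +
#'   \Delta^{14}C_{young} f_{young}, \qquad f_{old} + f_{young} = 1,}
#' solved as \eqn{f_{old} = (\Delta^{14}C_{young} - \Delta^{14}C_{CO_2}) /
#' (\Delta^{14}C_{young} - \Delta^{14}C_{old})}. Fractions outside [0, 1]
#' are clamped to the boundary and flagged, keeping cohort summaries
#' computable under measurement noise.
#'
#' @param delta14c_co2 \eqn{\Delta^{14}}C of respired CO2 (permil).
#' @param delta14c_old old endmember (permil): the bulk-SOC signature, -1000
#'   for radiocarbon-dead petrogenic carbon, or an inferred MAOC signature.
#' @param delta14c_young young endmember (permil), normally the atmospheric
#'   \eqn{\Delta^{14}}C in the sampling year.
#' @param assumption optional label recorded with the result (e.g.
#'   \code{"bulk_soc"}, \code{"petrogenic"}, \code{"maoc"}).
#'
#' @return A data frame with columns \code{f_old}, \code{f_young},
#'   \code{assumption}, \code{endmember_old}, \code{endmember_young} and
#'   logical \code{clamped}.
#' @examples
#' f_old(-39.2, -1000, 0)$f_old   # 0.0392
#' f_old(-39.2, -190, 0)$f_old    # 0.2063
#' @export
f_old <- function(delta14c_co2, delta14c_old, delta14c_young,
                  assumption = NA_character_) {
  if (any(delta14c_old == delta14c_young, na.rm = TRUE))
    stop("old and young endmembers are equal: mixture unidentifiable",
         call. = FALSE)
  raw <- (delta14c_young - delta14c_co2) / (delta14c_young - delta14c_old)
  clamped <- raw < 0 | raw > 1
  f <- pmin(pmax(raw, 0), 1)
  data.frame(f_old = f, f_young = 1 - f, assumption = assumption,
             endmember_old = delta14c_old,
             endmember_young = delta14c_young, clamped = clamped)
}

#' Delta14C of mineral-associated organic carbon by mass balance
#'
#' Assuming particulate organic carbon (POC) is fast-cycling with a modern
#' signature (\eqn{\Delta^{14}C_{POC} \approx 0}), the bulk mass balance
#' \eqn{\Delta^{14}C_{bulk} = \Delta^{14}C_{POC} w_{POC} +
#' \Delta^{14}C_{MAOC} w_{MAOC}} reduces to
#' \eqn{\Delta^{14}C_{MAOC} = \Delta^{14}C_{bulk} / w_{MAOC}}. Results below
#' the physical floor of -1000 permil indicate the modern-POC assumption is
#' untenable for that site; they are returned as-is with a warning and
#' marked in the \code{"infeasible"} attribute.
#'
#' @param bulk_delta14c bulk SOC \eqn{\Delta^{14}}C (permil).
#' @param w_maoc MAOC fraction of SOC, in (0, 1].
#'
#' @return \eqn{\Delta^{14}}C of MAOC (permil), with a logical attribute
#'   \code{"infeasible"}.
#' @examples
#' maoc_delta14c(-200, 0.8)  # -250
#' @export
maoc_delta14c <- function(bulk_delta14c, w_maoc) {
  if (any(!is.finite(w_maoc)) || any(w_maoc <= 0) || any(w_maoc > 1))
    stop("w_maoc must be in (0, 1]", call. = FALSE)
  out <- bulk_delta14c / w_maoc
  infeasible <- out < -1000
  if (any(infeasible, na.rm = TRUE))
    warning("inferred Delta14C_MAOC below -1000 permil for ",
            sum(infeasible, na.rm = TRUE),
            " value(s): modern-POC assumption infeasible", call. = FALSE)
  attr(out, "infeasible") <- infeasible
  out
}

#' Old-carbon mixing under all endmember assumptions
#'
#' Evaluates \code{\link{f_old}} for one site under the three old-endmember
#' assumptions: the bulk-SOC signature (high-end estimate), radiocarbon-dead
#' petrogenic carbon at -1000 permil (low-end), and, when POC/MAOC fractions
#' are available, the inferred MAOC signature. The young endmember is the
#' atmospheric \eqn{\Delta^{14}}C in the sampling year (or 0 permil if
#' \code{config$young_endmember_zero}).
#'
#' @param site a one-row data frame or list with \code{delta14c_co2},
#'   \code{delta14c_bulk}, \code{sampling_year} and optionally
#'   \code{w_maoc}.
#' @param curve atmospheric curve supplying the young endmember.
#' @param config an \code{\link{arid14c_config}}.
#'
#' @return A data frame with one row per applicable assumption (columns as
#'   in \code{\link{f_old}}).
#' @export
f_old_suite <- function(site, curve, config = arid14c_config()) {
  site <- as.list(site)
  if (is.null(site$delta14c_co2) || !is.finite(site$delta14c_co2))
    stop("site lacks a respired Delta14C value", call. = FALSE)
  if (is.null(site$delta14c_bulk) || !is.finite(site$delta14c_bulk))
    stop("site lacks a bulk Delta14C value", call. = FALSE)
  young <- if (isTRUE(config$young_endmember_zero)) 0 else
    atm_delta14c(curve, site$sampling_year)

  out <- rbind(
    f_old(site$delta14c_co2, site$delta14c_bulk, young, "bulk_soc"),
    f_old(site$delta14c_co2, -1000, young, "petrogenic"))
  if (!is.null(site$w_maoc) && is.finite(site$w_maoc)) {
    maoc <- suppressWarnings(maoc_delta14c(site$delta14c_bulk, site$w_maoc))
    if (!attr(maoc, "infeasible")) {
      out <- rbind(out,
                   f_old(site$delta14c_co2, as.numeric(maoc), young, "maoc"))
    }
  }
  out
}
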