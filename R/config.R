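#' Analysis configuration
#'
#' Central configuration for the screening, mixing, pool-fitting and
#' threshold stages. Call with name = value pairs to override defaults;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{sic_content_floor}{0.001 — SIC mass fraction (i.e. 0.1 mass-\% C)
#'     below which all respired CO2 is attributed to SOC.}
#'   \item{f_sic_exclusion}{0.15 — sites whose carbonate share of respired
#'     CO2 exceeds this are excluded from respiration analyses.}
#'   \item{d13c_separation_floor}{2.0 — minimum \eqn{\delta^{13}}C separation
#'     (permil) between the SOC and carbonate endmembers for the partition to
#'     be identifiable.}
#'   \item{calcite_co2_fractionation}{9.6 — calcite–CO2 equilibrium
#'     fractionation (permil) at the 20 degC incubation temperature.}
#'   \item{delta14c_sic_endmember}{-1000 — \eqn{\Delta^{14}}C (permil) of
#'     carbonate-derived CO2 used when a site has no measured SIC
#'     \eqn{\Delta^{14}}C (radiocarbon-dead parent-material carbonate).}
#'   \item{excluded_regions}{character(0) — regions dropped from respiration
#'     analyses regardless of screening (dataset-specific judgment).}
#'   \item{young_endmember_zero}{FALSE — if TRUE the young mixing endmember is
#'     fixed at 0 permil instead of the atmospheric value in the sampling
#'     year (sensitivity runs).}
#'   \item{k_grid_min, k_grid_max, k_grid_points}{1e-5, 10, 2000 — log-spaced
#'     decay-rate grid (yr^-1) scanned by \code{\link{fit_one_pool}}.}
#'   \item{fit_tolerance_permil}{0.1 — one-pool root refinement tolerance.}
#'   \item{two_pool_tolerance_permil}{1 — residual (permil) below which a
#'     two-pool profile member counts as reproducing both observations.}
#'   \item{two_pool_structure}{"parallel" — default two-pool topology.}
#'   \item{k_fast_profile_grid}{25 log-spaced values in [0.02, 2] yr^-1 —
#'     fast-pool rates profiled by \code{\link{fit_two_pool}}.}
#'   \item{k_slow_bounds}{c(1e-5, 0.1) — slow-pool rate search bounds.}
#'   \item{breakpoint_edge_margin}{0.05 — fraction of the x-range excluded
#'     from candidate breakpoints at each edge.}
#'   \item{breakpoint_min_side}{5 — minimum points required on each side of a
#'     candidate breakpoint.}
#'   \item{bootstrap_n}{499 — bootstrap resamples for the breakpoint CI.}
#'   \item{seed}{1 — seed for the (bootstrap) randomness in a pipeline run.}
#' }
#'
#' @return A named list with class \code{"arid14c_config"}.
#' @examples
#' cfg <- arid14c_config(f_sic_exclusion = 0.10)
#' cfg$f_sic_exclusion
#' @export
arid14c_config <- function(...) {
  defaults <- list(
    sic_content_floor = 0.001,
    f_sic_exclusion = 0.15,
    d13c_separation_floor = 2.0,
    calcite_co2_fractionation = 9.6,
    delta14c_sic_endmember = -1000,
    excluded_regions = character(0),
    young_endmember_zero = FALSE,
    k_grid_min = 1e-5,
    k_grid_max = 10,
    k_grid_points = 2000,
    fit_tolerance_permil = 0.1,
    two_pool_tolerance_permil = 1,
    two_pool_structure = "parallel",
    k_fast_profile_grid = exp(seq(log(0.02), log(2), length.out = 25)),
    k_slow_bounds = c(1e-5, 0.1),
    breakpoint_edge_margin = 0.05,
    breakpoint_min_side = 5,
    bootstrap_n = 499,
    seed = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[nm] <- overrides
  }
  structure(defaults, class = "arid14c_config")
}
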