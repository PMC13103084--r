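# Pipeline orchestration: corrections -> carbonate partition/screening ->
# old-carbon mixing -> pool fitting -> cohort summaries and threshold fits.

SITE_SCHEMA <- c("site_id", "region", "sampling_year", "aridity", "mat",
                 "map_mm", "npp", "plant_cover", "species_richness", "soc",
                 "sic", "ph", "clay_silt", "fe_al", "resp_rate", "d13c_tc",
                 "d13c_soc", "d13c_sic", "d13c_co2", "f14c_bulk",
                 "delta14c_bulk", "f14c_co2", "delta14c_co2", "w_poc",
                 "w_maoc")

#' Read a site table
#'
#' Reads the pipeline's site CSV (one row per site; empty cells are
#' missing) and validates the schema.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_sites <- function(path) {
  validate_sites(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a site table against the pipeline schema
#'
#' Checks required columns, that every site has either a Fraction Modern or
#' a \eqn{\Delta^{14}}C value for the bulk pool, and basic domain
#' constraints. Offending rows are listed in the error.
#'
#' @param sites data frame of sites.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_sites <- function(sites) {
  sites <- as.data.frame(sites)
  missing_cols <- setdiff(SITE_SCHEMA, names(sites))
  if (length(missing_cols))
    stop("site table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(is.na(sites$f14c_bulk) & is.na(sites$delta14c_bulk))
  if (length(bad))
    stop("site rows without bulk F14C or Delta14C: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad_year <- which(!is.finite(sites$sampling_year))
  if (length(bad_year))
    stop("site rows without a sampling year: ",
         paste(utils::head(bad_year, 10), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id values", call. = FALSE)
  sites
}

#' Difference between respired and bulk Delta14C
#'
#' Returns respired minus bulk (\code{delta14c_co2 - delta14c_bulk}), so a
#' positive difference means the respired CO2 is younger (less
#' radiocarbon-depleted) than the bulk SOC. With this sign convention the
#' difference increases along the aridity gradient.
#'
#' @param delta14c_co2,delta14c_bulk \eqn{\Delta^{14}}C of respired CO2 and
#'   bulk SOC (permil); both must be present.
#' @return Difference (permil).
#' @examples
#' difference_bulk_respired(-39.2, -190.0)  # +150.8
#' @export
difference_bulk_respired <- function(delta14c_co2, delta14c_bulk) {
  if (any(!is.finite(delta14c_co2)) || any(!is.finite(delta14c_bulk)))
    stop("both respired and bulk Delta14C are required", call. = FALSE)
  delta14c_co2 - delta14c_bulk
}

.mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Run the full radiocarbon analysis pipeline over a site table
#'
#' Per site: background-corrected \eqn{\Delta^{14}}C (computed from Fraction
#' Modern where only that is given), the carbonate partition and screening
#' status, the old-carbon mixing suite, one-pool fits of bulk (all sites)
#' and respired (included sites) \eqn{\Delta^{14}}C, and the
#' respired-minus-bulk difference. At cohort level: means and standard
#' errors, a two-pool fit to the cohort means, both ways of summarizing
#' f_old (mean of site-level fractions, and the fraction implied by the
#' cohort-mean inputs), and breakpoint fits of bulk/respired/difference
#' \eqn{\Delta^{14}}C against aridity. Deterministic given
#' \code{config$seed}.
#'
#' @param sites site data frame (or CSV path) in the pipeline schema.
#' @param curve atmospheric forcing curve.
#' @param config an \code{\link{arid14c_config}}.
#' @param two_pool fit the cohort-level two-pool model? (slowest stage)
#' @param breakpoints fit aridity threshold models?
#'
#' @return An object of class \code{"arid14c_result"}: \code{per_site}
#'   (one row per input site), \code{summary} (cohort statistics),
#'   \code{two_pool}, \code{breakpoints}, \code{config}.
#' @examples
#' \donttest{
#' sites <- generate_sites(scenario_config(n_sites = 15, seed = 7))
#' res <- run_pipeline(sites, two_pool = FALSE, breakpoints = FALSE)
#' res$summary$delta14c_bulk
#' }
#' @export
run_pipeline <- function(sites, curve = synthetic_bomb_curve(),
                         config = arid14c_config(), two_pool = TRUE,
                         breakpoints = TRUE) {
  if (is.character(sites)) sites <- read_sites(sites)
  sites <- validate_sites(sites)
  n <- nrow(sites)

  # isotope corrections: prefer reported Delta14C, else derive from F14C
  atm_y <- atm_delta14c(curve, sites$sampling_year)
  d14c_bulk <- sites$delta14c_bulk
  i <- which(is.na(d14c_bulk) & !is.na(sites$f14c_bulk))
  if (length(i))
    d14c_bulk[i] <- f14c_to_delta14c(sites$f14c_bulk[i],
                                     sites$sampling_year[i]) - atm_y[i]
  d14c_co2 <- sites$delta14c_co2
  i <- which(is.na(d14c_co2) & !is.na(sites$f14c_co2))
  if (length(i))
    d14c_co2[i] <- f14c_to_delta14c(sites$f14c_co2[i],
                                    sites$sampling_year[i]) - atm_y[i]

  # carbonate signature from total-C mass balance where not measured
  d13c_sic <- sites$d13c_sic
  derivable <- is.na(d13c_sic) & !is.na(sites$d13c_tc) &
    !is.na(sites$d13c_soc) & !is.na(sites$sic) & sites$sic > 0
  if (any(derivable)) {
    i <- which(derivable)
    d13c_sic[i] <- suppressWarnings(delta13c_sic(
      sites$d13c_tc[i], sites$soc[i] + sites$sic[i],
      sites$d13c_soc[i], sites$soc[i], sites$sic[i]))
  }

  part <- sic_partition(sites$d13c_co2, sites$d13c_soc, d13c_sic,
                        sites$sic, d14c_co2, sites$region,
                        config = config)
  has_resp <- is.finite(d14c_co2)
  included <- has_resp &
    part$status %in% c("assumed_zero_sic", "included_original")

  # old-carbon mixing under the three endmember assumptions
  young <- if (isTRUE(config$young_endmember_zero)) 0 else atm_y
  mix_bulk <- mix_petro <- mix_maoc <- rep(NA_real_, n)
  for (i in which(included)) {
    suite <- f_old_suite(list(delta14c_co2 = d14c_co2[i],
                              delta14c_bulk = d14c_bulk[i],
                              sampling_year = sites$sampling_year[i],
                              w_maoc = sites$w_maoc[i]), curve, config)
    mix_bulk[i] <- suite$f_old[suite$assumption == "bulk_soc"]
    mix_petro[i] <- suite$f_old[suite$assumption == "petrogenic"]
    if ("maoc" %in% suite$assumption)
      mix_maoc[i] <- suite$f_old[suite$assumption == "maoc"]
  }

  # one-pool fits: bulk for every site, respired for included sites
  age_bulk <- age_resp <- n_solutions_resp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- try(fit_one_pool(d14c_bulk[i], curve, sites$sampling_year[i],
                            config), silent = TRUE)
    if (!inherits(fit, "try-error")) age_bulk[i] <- fit$age_years
    if (included[i]) {
      fit <- try(fit_one_pool(d14c_co2[i], curve, sites$sampling_year[i],
                              config), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        age_resp[i] <- fit$age_years
        n_solutions_resp[i] <- fit$n_solutions
      }
    }
  }

  difference <- rep(NA_real_, n)
  difference[included] <- d14c_co2[included] - d14c_bulk[included]

  per_site <- data.frame(
    site_id = sites$site_id, region = sites$region,
    sampling_year = sites$sampling_year, aridity = sites$aridity,
    delta14c_bulk = d14c_bulk, delta14c_co2 = d14c_co2,
    d13c_sic_eq = part$d13c_sic_eq, f_sic = part$f_sic,
    delta14c_co2_soc = part$delta14c_co2_soc, status = part$status,
    included_resp = included, difference = difference,
    f_old_bulk = mix_bulk, f_old_petro = mix_petro, f_old_maoc = mix_maoc,
    age_bulk = age_bulk, transit_resp = age_resp,
    n_solutions_resp = n_solutions_resp)

  mb <- .mean_se(d14c_bulk)
  mr <- .mean_se(d14c_co2[included])
  young_mean <- if (isTRUE(config$young_endmember_zero)) 0 else
    atm_delta14c(curve, mean(sites$sampling_year[included]))
  summary <- list(
    n_total = n, n_included_resp = sum(included),
    delta14c_bulk = mb, delta14c_co2 = mr,
    difference = .mean_se(difference),
    age_bulk = .mean_se(age_bulk),
    transit_resp = .mean_se(age_resp),
    f_old_site_mean = c(bulk_soc = mean(mix_bulk, na.rm = TRUE),
                        petrogenic = mean(mix_petro, na.rm = TRUE),
                        maoc = mean(mix_maoc, na.rm = TRUE)),
    f_old_of_means = c(
      bulk_soc = as.numeric(
        f_old(mr[["mean"]], mb[["mean"]], young_mean)$f_old),
      petrogenic = as.numeric(
        f_old(mr[["mean"]], -1000, young_mean)$f_old)))

  two_pool_fit_res <- NULL
  if (two_pool && sum(included) > 0) {
    two_pool_fit_res <- try(fit_two_pool(
      mb[["mean"]], mr[["mean"]], config$two_pool_structure, curve,
      stats::median(sites$sampling_year), config), silent = TRUE)
    if (inherits(two_pool_fit_res, "try-error")) two_pool_fit_res <- NULL
  }

  bp <- NULL
  if (breakpoints && n >= 10) {
    bp <- list(
      bulk_vs_aridity = try(fit_breakpoint(
        sites$aridity, d14c_bulk, config), silent = TRUE),
      respired_vs_aridity = try(fit_breakpoint(
        sites$aridity[included], d14c_co2[included], config),
        silent = TRUE),
      difference_vs_aridity = try(fit_breakpoint(
        sites$aridity[included], difference[included], config),
        silent = TRUE))
    bp <- lapply(bp, function(f)
      if (inherits(f, "try-error")) NULL else f)
  }

  structure(list(per_site = per_site, summary = summary,
                 two_pool = two_pool_fit_res, breakpoints = bp,
                 config = config),
            class = "arid14c_result")
}

#' @export
print.arid14c_result <- function(x, ...) {
  s <- x$summary
  cat("Dryland radiocarbon pipeline result\n")
  cat(sprintf("  %d sites; %d included in respiration analyses\n",
              s$n_total, s$n_included_resp))
  cat(sprintf("  bulk Delta14C     %7.1f +/- %.1f permil\n",
              s$delta14c_bulk["mean"], s$delta14c_bulk["se"]))
  cat(sprintf("  respired Delta14C %7.1f +/- %.1f permil\n",
              s$delta14c_co2["mean"], s$delta14c_co2["se"]))
  cat(sprintf("  difference (respired - bulk) %7.1f +/- %.1f permil\n",
              s$difference["mean"], s$difference["se"]))
  cat(sprintf("  one-pool mean age (bulk)    %6.0f +/- %.0f y\n",
              s$age_bulk["mean"], s$age_bulk["se"]))
  cat(sprintf("  one-pool transit (respired) %6.0f +/- %.0f y\n",
              s$transit_resp["mean"], s$transit_resp["se"]))
  f <- s$f_old_site_mean
  cat(sprintf(
    "  f_old (site means): bulk-SOC %.1f%%, petrogenic %.1f%%, MAOC %.1f%%\n",
    100 * f["bulk_soc"], 100 * f["petrogenic"], 100 * f["maoc"]))
  if (!is.null(x$two_pool))
    cat(sprintf(
      "  two-pool (%s): transit %.0f y, slow pool %.0f%% of stock\n",
      x$two_pool$structure, x$two_pool$mean_transit_time,
      100 * x$two_pool$mass_frac_slow))
  if (!is.null(x$breakpoints$bulk_vs_aridity))
    cat(sprintf("  bulk Delta14C aridity threshold: psi = %.3f (%s)\n",
                x$breakpoints$bulk_vs_aridity$psi,
                compare_aic(x$breakpoints$bulk_vs_aridity)))
  invisible(x)
}
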