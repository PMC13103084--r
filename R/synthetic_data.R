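# Synthetic site generator. Emulates the statistical structure of a global
# dryland radiocarbon survey: ~97 sites along an aridity gradient, bulk SOC
# dominated by centuries- to millennia-old carbon, respired CO2 younger
# than bulk SOC, carbonate (SIC) contamination of respired CO2 at a subset
# of sites, and POC/MAOC fractionation data for a subset. Every site
# carries hidden generating parameters so pipeline stages can be checked by
# parameter recovery.

#' Scenario configuration for the synthetic site generator
#'
#' Defaults emulate the survey conditions: 97 sites with aridity
#' (1 - aridity index) spanning 0.46--0.99, MAT -3.4 to 24 degC, sampling
#' years 2015--2020, roughly 46\% of sites effectively carbonate-free, and
#' POC/MAOC fractions for 41 sites. Bulk mean ages follow
#' \eqn{\ln(age) = a_0 + a_1 \cdot aridity + a_2 (aridity - \psi)_+ +
#' \epsilon}, an aridity trend with an embedded breakpoint; respired-carbon
#' ages are a noisy fraction of the bulk age. The age-model coefficients are
#' calibrated once so that cohort mean \eqn{\Delta^{14}}C is about -190
#' permil (bulk) and -39 permil (respired), with bulk values spanning
#' roughly -420 to -5 permil.
#'
#' @param n_sites number of sites (>= 10).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param aridity_range,mat_range covariate ranges.
#' @param sampling_years years sites may be sampled in.
#' @param age_intercept,age_aridity_slope,age_breakpoint_slope,age_breakpoint_psi,age_sigma
#'   coefficients of the log-age model (slopes per unit aridity; psi on the
#'   aridity scale; sigma is the log-scale site scatter).
#' @param resp_age_ratio,resp_age_sigma respired-pool age as a lognormal
#'   multiple of the bulk age.
#' @param noise_delta14c,noise_d13c Gaussian measurement noise (permil).
#' @param sic_zero_prob probability a site's SIC content is below the 0.1\%
#'   screening floor.
#' @param f_sic_beta shape parameters of the Beta draw for the true
#'   carbonate share of respired CO2 at carbonate-bearing sites.
#' @param sic_endmember_delta14c \eqn{\Delta^{14}}C of carbonate-derived CO2
#'   in the forward model (permil).
#' @param d13c_soc_mean,d13c_soc_sd,d13c_sic_mean,d13c_sic_sd
#'   \eqn{\delta^{13}}C endmember distributions (permil).
#' @param poc_maoc_n number of sites carrying POC/MAOC fractions; defaults
#'   to the 41/97 share of \code{n_sites}.
#' @param regions region labels sites are assigned to.
#'
#' @return A named list with class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_sites = 97, seed = 1,
                            aridity_range = c(0.46, 0.99),
                            mat_range = c(-3.4, 24.0),
                            sampling_years = 2015:2020,
                            age_intercept = 6.1,
                            age_aridity_slope = 1.75,
                            age_breakpoint_slope = 6,
                            age_breakpoint_psi = 0.87,
                            age_sigma = 0.35,
                            resp_age_ratio = 0.17,
                            resp_age_sigma = 0.4,
                            noise_delta14c = 3,
                            noise_d13c = 0.3,
                            sic_zero_prob = 45 / 97,
                            f_sic_beta = c(1, 7),
                            sic_endmember_delta14c = -1000,
                            d13c_soc_mean = -24, d13c_soc_sd = 1.5,
                            d13c_sic_mean = 0, d13c_sic_sd = 1,
                            poc_maoc_n = NULL,
                            regions = c("Argentina", "Australia",
                                        "China alpine",
                                        "China Loess Plateau",
                                        "China east", "China west", "Iran",
                                        "South Africa", "Spain",
                                        "United States")) {
  if (n_sites < 10) stop("n_sites must be at least 10", call. = FALSE)
  if (diff(aridity_range) <= 0 || any(aridity_range <= 0) ||
      any(aridity_range >= 1))
    stop("aridity_range must be increasing and inside (0, 1)",
         call. = FALSE)
  if (is.null(poc_maoc_n)) poc_maoc_n <- round(n_sites * 41 / 97)
  if (poc_maoc_n > n_sites)
    stop("poc_maoc_n cannot exceed n_sites", call. = FALSE)
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a synthetic dryland site table
#'
#' Draws covariates, assigns each site true one-pool ages for its bulk and
#' respired carbon, forward-simulates \eqn{\Delta^{14}}C through the pool
#' model under \code{curve}, composes the \eqn{\delta^{13}}C observables
#' from the true carbonate share, and adds Gaussian measurement noise. Both
#' \eqn{\Delta^{14}}C and the equivalent Fraction Modern columns are
#' emitted, so either input path of the pipeline can be exercised.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param curve atmospheric forcing curve used in the forward simulation.
#'
#' @return A data frame in the pipeline's site CSV schema, with the hidden
#'   generating parameters attached as a data frame in
#'   \code{attr(, "truth")} (columns \code{site_id},
#'   \code{age_bulk_true}, \code{age_resp_true}, \code{k_bulk_true},
#'   \code{k_resp_true}, \code{f_sic_true}, \code{f_old_true}).
#' @examples
#' sites <- generate_sites(scenario_config(n_sites = 12, seed = 42))
#' head(attr(sites, "truth"))
#' @export
generate_sites <- function(config = scenario_config(),
                           curve = synthetic_bomb_curve()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, .generate_sites_impl(config, curve))
}

.generate_sites_impl <- function(cfg, curve) {
  n <- cfg$n_sites
  aridity <- stats::runif(n, cfg$aridity_range[1], cfg$aridity_range[2])
  region <- sample(cfg$regions, n, replace = TRUE)
  sampling_year <- sample(cfg$sampling_years, n, replace = TRUE)
  mat <- stats::runif(n, cfg$mat_range[1], cfg$mat_range[2])
  arid_scaled <- (aridity - cfg$aridity_range[1]) / diff(cfg$aridity_range)
  map_mm <- pmin(754, pmax(28, round(
    28 + (754 - 28) * (1 - arid_scaled) * exp(stats::rnorm(n, 0, 0.15)))))
  npp <- exp(6.5 - 3 * aridity + stats::rnorm(n, 0, 0.3))
  plant_cover <- pmin(100, pmax(1,
    100 * (1 - aridity) * exp(stats::rnorm(n, 0, 0.3))))
  species_richness <- stats::rpois(n, pmax(2, 25 * (1 - aridity)))
  soc <- exp(1.5 - 2.5 * aridity + stats::rnorm(n, 0, 0.5))
  ph <- pmin(10, pmax(5, 6.5 + 2.5 * aridity + stats::rnorm(n, 0, 0.3)))
  clay_silt <- stats::runif(n, 10, 70)
  fe_al <- exp(stats::rnorm(n, log(2), 0.5))
  resp_rate <- exp(0.8 + 0.8 * log(soc) + stats::rnorm(n, 0, 0.4))

  # true one-pool parameters from the log-age model
  ln_age_bulk <- cfg$age_intercept + cfg$age_aridity_slope * aridity +
    cfg$age_breakpoint_slope * pmax(0, aridity - cfg$age_breakpoint_psi) +
    stats::rnorm(n, 0, cfg$age_sigma)
  age_bulk <- pmin(5800, pmax(30, exp(ln_age_bulk)))
  age_resp <- exp(log(age_bulk) + log(cfg$resp_age_ratio) +
                    stats::rnorm(n, 0, cfg$resp_age_sigma))
  age_resp <- pmin(age_bulk, pmin(1500, pmax(3, age_resp)))
  k_bulk <- 1 / age_bulk
  k_resp <- 1 / age_resp

  d14c_bulk_true <- d14c_resp_true <- numeric(n)
  for (yr in unique(sampling_year)) {
    i <- sampling_year == yr
    d14c_bulk_true[i] <- simulate_one_pool(k_bulk[i], curve, yr)
    d14c_resp_true[i] <- simulate_one_pool(k_resp[i], curve, yr)
  }

  # carbonate prevalence: zero-inflated SIC content
  sic_free <- stats::runif(n) < cfg$sic_zero_prob
  sic <- ifelse(sic_free, stats::runif(n, 0, 0.099),
                pmin(10, exp(stats::rnorm(n, log(1), 0.8))))
  f_sic_true <- ifelse(sic_free, 0,
                       stats::rbeta(n, cfg$f_sic_beta[1], cfg$f_sic_beta[2]))

  d13c_soc <- stats::rnorm(n, cfg$d13c_soc_mean, cfg$d13c_soc_sd)
  d13c_sic <- stats::rnorm(n, cfg$d13c_sic_mean, cfg$d13c_sic_sd)
  d13c_co2 <- f_sic_true * (d13c_sic - 9.6) +
    (1 - f_sic_true) * d13c_soc + stats::rnorm(n, 0, cfg$noise_d13c)
  w_tc <- soc + sic
  d13c_tc <- (d13c_soc * soc + d13c_sic * sic) / w_tc

  delta14c_bulk <- d14c_bulk_true + stats::rnorm(n, 0, cfg$noise_delta14c)
  delta14c_co2 <- f_sic_true * cfg$sic_endmember_delta14c +
    (1 - f_sic_true) * d14c_resp_true +
    stats::rnorm(n, 0, cfg$noise_delta14c)
  delta14c_bulk <- pmax(delta14c_bulk, -999.9)
  delta14c_co2 <- pmax(delta14c_co2, -999.9)

  atm_y <- atm_delta14c(curve, sampling_year)
  f14c_bulk <- delta14c_to_f14c(delta14c_bulk + atm_y, sampling_year)
  f14c_co2 <- delta14c_to_f14c(delta14c_co2 + atm_y, sampling_year)

  w_maoc <- rep(NA_real_, n)
  has_frac <- sample.int(n, cfg$poc_maoc_n)
  w_maoc[has_frac] <- stats::runif(cfg$poc_maoc_n, 0.6, 0.95)
  w_poc <- 1 - w_maoc

  site_id <- sprintf("S%03d", seq_len(n))
  sites <- data.frame(
    site_id = site_id, region = region, sampling_year = sampling_year,
    aridity = aridity, mat = mat, map_mm = map_mm, npp = npp,
    plant_cover = plant_cover, species_richness = species_richness,
    soc = soc, sic = sic, ph = ph, clay_silt = clay_silt, fe_al = fe_al,
    resp_rate = resp_rate, d13c_tc = d13c_tc, d13c_soc = d13c_soc,
    d13c_sic = ifelse(sic < 0.1, NA_real_, d13c_sic),
    d13c_co2 = d13c_co2, f14c_bulk = f14c_bulk,
    delta14c_bulk = delta14c_bulk, f14c_co2 = f14c_co2,
    delta14c_co2 = delta14c_co2, w_poc = w_poc, w_maoc = w_maoc)

  attr(sites, "truth") <- data.frame(
    site_id = site_id, age_bulk_true = age_bulk, age_resp_true = age_resp,
    k_bulk_true = k_bulk, k_resp_true = k_resp, f_sic_true = f_sic_true,
    f_old_true = (atm_y - d14c_resp_true) / (atm_y - d14c_bulk_true))
  attr(sites, "seed") <- cfg$seed
  sites
}

#' Incubation sampling gate
#'
#' Headspace gas is only sampled for isotope analysis once enough CO2 has
#' accumulated: the cumulative respired carbon must reach 1\% of total soil
#' carbon and at least 0.2 mg C in total.
#'
#' @param cumulative_respired_c cumulative respired carbon (mg).
#' @param total_soil_c total soil carbon in the incubated sample (mg).
#' @return Logical: may the headspace be sampled?
#' @examples
#' incubation_gate(2.0, 150)   # TRUE
#' incubation_gate(0.1, 5)     # FALSE (below 0.2 mg floor)
#' incubation_gate(0.25, 50)   # FALSE (below 1 percent)
#' @export
incubation_gate <- function(cumulative_respired_c, total_soil_c) {
  if (any(cumulative_respired_c < 0 | total_soil_c < 0, na.rm = TRUE))
    stop("inputs must be non-negative", call. = FALSE)
  cumulative_respired_c >= 0.01 * total_soil_c &
    cumulative_respired_c >= 0.2
}

#' Write a synthetic site table and its truth sidecar
#'
#' Writes the site table to \code{path} and the hidden generating
#' parameters to a \code{*_truth.csv} sidecar next to it.
#'
#' @param sites output of \code{\link{generate_sites}}.
#' @param path CSV path for the site table.
#' @return Invisibly, the truth sidecar path.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, na = "")
  truth <- attr(sites, "truth")
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.csv")
  if (!is.null(truth))
    utils::write.csv(truth, truth_path, row.names = FALSE, na = "")
  invisible(truth_path)
}
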