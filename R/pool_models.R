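# One- and two-pool steady-state radiocarbon models under atmospheric
# forcing. The state variable is an absolute fraction-modern ratio F in
# which the atmosphere is F_atm(t) = Delta14C_atm(t)/1000 + 1; pools obey
#   dF/dt = k (F_atm(t) - F) - lambda F
# and are initialized in 1900 at the pre-bomb steady state
# F0 = k/(k + lambda) F_atm(1900). Each model year is advanced with the
# exact exponential solution holding the forcing at its year-midpoint
# value, which is unconditionally stable over the whole fitted k range and
# reproduces the flat-atmosphere steady state exactly.

# Mass balance uses k only (radioactive loss is isotopic bookkeeping, not a
# carbon flux of any practical size), so steady-state stocks are input/k.

# Advance pool(s) from 1900 to sample_year; vectorized over k.
# keep_path returns the (n_steps + 1) x length(k) matrix of F at step
# boundaries, needed to force the slow pool of a series model.
.fm_run <- function(k, curve, sample_year, keep_path = FALSE) {
  lam <- LAMBDA_14C
  t0 <- 1900
  n_full <- floor(sample_year - t0 + 1e-9)
  frac <- sample_year - t0 - n_full
  if (frac < 1e-9) frac <- 0
  mids <- if (n_full > 0) t0 + seq_len(n_full) - 0.5 else numeric(0)
  if (frac > 0) mids <- c(mids, t0 + n_full + frac / 2)
  fa <- atm_delta14c(curve, mids) / 1000 + 1
  h <- c(rep(1, n_full), if (frac > 0) frac)

  f <- k / (k + lam) * (atm_delta14c(curve, t0) / 1000 + 1)
  path <- if (keep_path)
    matrix(NA_real_, nrow = length(h) + 1, ncol = length(k)) else NULL
  if (keep_path) path[1, ] <- f
  decay <- exp(-(k + lam))  # full-year factor, reused
  for (i in seq_along(h)) {
    cc <- k * fa[i] / (k + lam)
    fac <- if (h[i] == 1) decay else exp(-(k + lam) * h[i])
    f <- cc + (f - cc) * fac
    if (keep_path) path[i + 1, ] <- f
  }
  if (keep_path) list(f = f, path = path, h = h) else f
}

.fm_to_delta14c <- function(f, sample_year) {
  (f * exp(LAMBDA_14C * (1950 - sample_year)) - 1) * 1000
}

#' Simulate the Delta14C of a one-pool steady-state model
#'
#' Runs a single homogeneous pool with decay rate \code{k} from 1900 (at
#' its pre-bomb steady state) to \code{sample_year} under the given
#' atmospheric forcing, and returns its \eqn{\Delta^{14}}C in the sampling
#' year. With \code{background_correct = TRUE} (default) the atmospheric
#' \eqn{\Delta^{14}}C at \code{sample_year} is subtracted, matching the
#' convention of background-corrected observations.
#'
#' @param k decay rate (yr^-1), > 0; vectorized.
#' @param curve atmospheric forcing curve.
#' @param sample_year sampling year (possibly fractional), within the curve
#'   domain.
#' @param background_correct subtract the sampling-year atmosphere?
#'
#' @return \eqn{\Delta^{14}}C (permil), one value per \code{k}.
#' @examples
#' curve <- synthetic_bomb_curve()
#' simulate_one_pool(1 / 500, curve, 2018)
#' @export
simulate_one_pool <- function(k, curve, sample_year,
                              background_correct = TRUE) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("k must be finite and > 0", call. = FALSE)
  d <- .fm_to_delta14c(.fm_run(k, curve, sample_year), sample_year)
  if (background_correct) d <- d - atm_delta14c(curve, sample_year)
  d
}

#' Fit a one-pool model to an observed Delta14C
#'
#' Scans the decay rate over a log grid, locates every sign change of
#' (modelled - observed) \eqn{\Delta^{14}}C, and refines each root by
#' bisection. Bomb-influenced observations can admit two rates (a fast pool
#' still carrying bomb carbon and a slow pre-bomb pool); following the
#' dual-solution rule, the smaller rate (longer transit time) is selected,
#' with every root retained for audit.
#'
#' @param observed_delta14c background-corrected \eqn{\Delta^{14}}C
#'   (permil).
#' @param curve atmospheric forcing curve.
#' @param sample_year sampling year.
#' @param config an \code{\link{arid14c_config}} (grid and tolerance keys).
#'
#' @return An object of class \code{"one_pool_fit"}: list with \code{k},
#'   \code{age_years} (= 1/k = mean age = transit time = turnover time),
#'   \code{fitted_delta14c}, \code{residual}, \code{n_solutions},
#'   \code{selection} (\code{"unique"} or \code{"longer_transit"}),
#'   \code{all_ages}, \code{observed}, \code{sample_year}.
#' @examples
#' curve <- synthetic_bomb_curve()
#' fit <- fit_one_pool(-190, curve, 2018)
#' fit$age_years
#' @export
fit_one_pool <- function(observed_delta14c, curve, sample_year,
                         config = arid14c_config()) {
  if (!is.finite(observed_delta14c))
    stop("observed_delta14c must be a single finite value", call. = FALSE)
  kg <- exp(seq(log(config$k_grid_min), log(config$k_grid_max),
                length.out = config$k_grid_points))
  resid <- simulate_one_pool(kg, curve, sample_year) - observed_delta14c
  sc <- which(diff(sign(resid)) != 0)
  if (!length(sc))
    stop("observation outside model range: no rate in [",
         config$k_grid_min, ", ", config$k_grid_max,
         "] yr^-1 reproduces ", observed_delta14c, " permil",
         call. = FALSE)
  tol <- config$fit_tolerance_permil
  roots <- vapply(sc, function(i) {
    lo <- kg[i]; hi <- kg[i + 1]
    flo <- resid[i]
    mid <- sqrt(lo * hi)
    for (j in 1:200) {
      mid <- sqrt(lo * hi)
      fm <- simulate_one_pool(mid, curve, sample_year) - observed_delta14c
      if (abs(fm) < tol) break
      if (sign(fm) == sign(flo)) {
        lo <- mid; flo <- fm
      } else hi <- mid
    }
    mid
  }, numeric(1))
  k <- min(roots)
  fitted <- simulate_one_pool(k, curve, sample_year)
  structure(list(
    k = k, age_years = 1 / k, fitted_delta14c = fitted,
    residual = fitted - observed_delta14c,
    n_solutions = length(roots),
    selection = if (length(roots) > 1) "longer_transit" else "unique",
    all_ages = sort(1 / roots), observed = observed_delta14c,
    sample_year = sample_year), class = "one_pool_fit")
}

#' @export
print.one_pool_fit <- function(x, ...) {
  cat("One-pool steady-state radiocarbon fit\n")
  cat(sprintf("  observed %.1f permil (year %.1f) -> k = %.3g yr^-1,",
              x$observed, x$sample_year, x$k))
  cat(sprintf(" age = transit = %.0f y\n", x$age_years))
  if (x$n_solutions > 1)
    cat("  ", x$n_solutions, " solutions (",
        paste(round(x$all_ages), collapse = ", "),
        " y); longer transit selected\n", sep = "")
  invisible(x)
}

.check_two_pool_pars <- function(k_fast, k_slow, partition) {
  if (!is.finite(k_fast) || !is.finite(k_slow) || k_slow <= 0 ||
      k_fast < k_slow)
    stop("need k_fast >= k_slow > 0", call. = FALSE)
  if (!is.finite(partition) || partition < 0 || partition > 1)
    stop("partition must be in [0, 1]", call. = FALSE)
}

#' Simulate a two-pool steady-state model
#'
#' Parallel structure: two independent pools receive input fractions
#' \code{partition} (fast) and \code{1 - partition} (slow). Series
#' structure: all input enters the fast pool; a fraction \code{partition}
#' (a21) of its outflux transfers to the slow pool, the rest is respired.
#' Bulk \eqn{\Delta^{14}}C is stock-weighted, respired \eqn{\Delta^{14}}C is
#' flux-weighted.
#'
#' @param structure \code{"parallel"} or \code{"series"}.
#' @param k_fast,k_slow pool decay rates (yr^-1), \code{k_fast >= k_slow}.
#' @param partition input fraction to the fast pool (parallel) or fast-to-
#'   slow transfer fraction a21 (series), in [0, 1].
#' @param curve atmospheric forcing curve.
#' @param sample_year sampling year.
#' @param background_correct subtract the sampling-year atmosphere?
#'
#' @return Named numeric vector \code{c(bulk = , respired = )} (permil).
#' @examples
#' curve <- synthetic_bomb_curve()
#' simulate_two_pool("parallel", 1 / 10, 1 / 5000, 0.9, curve, 2018)
#' @export
simulate_two_pool <- function(structure = c("parallel", "series"),
                              k_fast, k_slow, partition, curve,
                              sample_year, background_correct = TRUE) {
  structure <- match.arg(structure)
  .check_two_pool_pars(k_fast, k_slow, partition)
  if (structure == "parallel") {
    f_fast <- .fm_run(k_fast, curve, sample_year)
    f_slow <- .fm_run(k_slow, curve, sample_year)
    c_fast <- partition / k_fast
    c_slow <- (1 - partition) / k_slow
    f_bulk <- if (c_slow == 0) f_fast else if (c_fast == 0) f_slow else
      (c_fast * f_fast + c_slow * f_slow) / (c_fast + c_slow)
    f_resp <- if (partition == 1) f_fast else if (partition == 0) f_slow else
      partition * f_fast + (1 - partition) * f_slow
  } else {
    run <- .fm_run(k_fast, curve, sample_year, keep_path = TRUE)
    f_fast <- run$f
    f_slow <- .fm_series_slow(k_slow, run, curve)
    c_fast <- 1 / k_fast
    c_slow <- partition / k_slow
    f_bulk <- if (c_slow == 0) f_fast else
      (c_fast * f_fast + c_slow * f_slow) / (c_fast + c_slow)
    f_resp <- if (partition == 0) f_fast else
      (1 - partition) * f_fast + partition * f_slow
  }
  d <- .fm_to_delta14c(c(bulk = f_bulk, respired = f_resp), sample_year)
  if (background_correct) d <- d - atm_delta14c(curve, sample_year)
  d
}

# Slow pool of a series model, forced by the fast pool's within-year mean.
.fm_series_slow <- function(k_slow, fast_run, curve) {
  lam <- LAMBDA_14C
  path <- fast_run$path
  h <- fast_run$h
  f <- k_slow / (k_slow + lam) * path[1, 1]
  for (i in seq_along(h)) {
    fin <- (path[i, 1] + path[i + 1, 1]) / 2
    cc <- k_slow * fin / (k_slow + lam)
    f <- cc + (f - cc) * exp(-(k_slow + lam) * h[i])
  }
  f
}

#' Fit a two-pool model to paired bulk and respired Delta14C
#'
#' Two observations cannot pin down three parameters (two rates plus a
#' partition), so the fast-pool rate is profiled over a fixed grid; at each
#' grid value the slow rate and partition are optimized to minimize the
#' squared residuals of the simulated bulk and respired \eqn{\Delta^{14}}C.
#' All profile members reproducing both observations within the configured
#' tolerance form the reported solution family; the returned point estimate
#' is the family member with the shortest mean transit time, and the full
#' profile is kept for audit.
#'
#' @param delta14c_bulk,delta14c_respired observed background-corrected
#'   \eqn{\Delta^{14}}C (permil).
#' @param structure \code{"parallel"} or \code{"series"} (default from
#'   \code{config$two_pool_structure}).
#' @param curve atmospheric forcing curve.
#' @param sample_year sampling year.
#' @param config an \code{\link{arid14c_config}}.
#'
#' @return An object of class \code{"two_pool_fit"}: the selected
#'   \code{k_fast}, \code{k_slow}, \code{partition}, derived
#'   \code{mass_frac_slow}, \code{resp_frac_slow}, \code{mean_system_age},
#'   \code{mean_transit_time}, \code{residuals}, plus \code{profile} (data
#'   frame over the k_fast grid) and \code{n_family}.
#' @examples
#' \donttest{
#' curve <- synthetic_bomb_curve()
#' fit <- fit_two_pool(-190, -39.2, "parallel", curve, 2018)
#' fit$mass_frac_slow
#' }
#' @export
fit_two_pool <- function(delta14c_bulk, delta14c_respired,
                         structure = NULL, curve, sample_year,
                         config = arid14c_config()) {
  if (!is.finite(delta14c_bulk) || !is.finite(delta14c_respired))
    stop("both bulk and respired observations are required", call. = FALSE)
  if (is.null(structure)) structure <- config$two_pool_structure
  structure <- match.arg(structure, c("parallel", "series"))
  obs <- c(delta14c_bulk, delta14c_respired)
  atm_now <- atm_delta14c(curve, sample_year)
  dec <- exp(LAMBDA_14C * (1950 - sample_year))
  lo_ks <- log(config$k_slow_bounds[1])

  rows <- lapply(config$k_fast_profile_grid, function(kf) {
    hi_ks <- log(min(kf, config$k_slow_bounds[2]))
    run <- .fm_run(kf, curve, sample_year, keep_path = TRUE)
    f_fast <- run$f
    slow_state <- function(ks) {
      if (structure == "parallel") .fm_run(ks, curve, sample_year)
      else .fm_series_slow(ks, run, curve)
    }
    predict_pair <- function(ks, p) {
      f_slow <- slow_state(ks)
      if (structure == "parallel") {
        c_fast <- p / kf; c_slow <- (1 - p) / ks
        f_bulk <- (c_fast * f_fast + c_slow * f_slow) /
          (c_fast + c_slow)
        f_resp <- p * f_fast + (1 - p) * f_slow
      } else {
        c_fast <- 1 / kf; c_slow <- p / ks
        f_bulk <- (c_fast * f_fast + c_slow * f_slow) / (c_fast + c_slow)
        f_resp <- (1 - p) * f_fast + p * f_slow
      }
      (c(f_bulk, f_resp) * dec - 1) * 1000 - atm_now
    }
    objective <- function(par) {
      ks <- exp(lo_ks + stats::plogis(par[1]) * (hi_ks - lo_ks))
      p <- stats::plogis(par[2])
      sum((predict_pair(ks, p) - obs)^2)
    }
    starts <- expand.grid(u = stats::qlogis(c(0.2, 0.5, 0.8)),
                          v = stats::qlogis(c(0.1, 0.5, 0.9)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      opt <- stats::optim(as.numeric(starts[s, ]), objective,
                          method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-12))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    ks <- exp(lo_ks + stats::plogis(best$par[1]) * (hi_ks - lo_ks))
    p <- stats::plogis(best$par[2])
    pred <- predict_pair(ks, p)
    mom <- .two_pool_moments(structure, kf, ks, p)
    data.frame(k_fast = kf, k_slow = ks, partition = p,
               resid_bulk = pred[1] - obs[1],
               resid_resp = pred[2] - obs[2],
               mass_frac_slow = mom["mass_frac_slow"],
               resp_frac_slow = mom["resp_frac_slow"],
               mean_system_age = mom["mean_system_age"],
               mean_transit_time = mom["mean_transit_time"])
  })
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  ok <- pmax(abs(profile$resid_bulk), abs(profile$resid_resp)) <
    config$two_pool_tolerance_permil
  if (!any(ok))
    stop("no parameter set reproduces both observations within ",
         config$two_pool_tolerance_permil, " permil", call. = FALSE)
  family <- profile[ok, , drop = FALSE]
  sel <- family[which.min(family$mean_transit_time), , drop = FALSE]
  structure(list(
    structure = structure,
    k_fast = sel$k_fast, k_slow = sel$k_slow, partition = sel$partition,
    mass_frac_slow = sel$mass_frac_slow,
    resp_frac_slow = sel$resp_frac_slow,
    mean_system_age = sel$mean_system_age,
    mean_transit_time = sel$mean_transit_time,
    residuals = c(bulk = sel$resid_bulk, respired = sel$resid_resp),
    n_family = sum(ok), profile = profile,
    observed = c(bulk = delta14c_bulk, respired = delta14c_respired),
    sample_year = sample_year), class = "two_pool_fit")
}

#' @export
print.two_pool_fit <- function(x, ...) {
  cat("Two-pool (", x$structure, ") steady-state radiocarbon fit\n",
      sep = "")
  cat(sprintf("  k_fast = %.3g, k_slow = %.3g yr^-1, partition = %.3f\n",
              x$k_fast, x$k_slow, x$partition))
  cat(sprintf(
    "  slow pool: %.1f%% of stock, %.1f%% of respiration\n",
    100 * x$mass_frac_slow, 100 * x$resp_frac_slow))
  cat(sprintf("  mean system age %.0f y, mean transit time %.0f y",
              x$mean_system_age, x$mean_transit_time))
  cat(sprintf("  (family of %d profile members)\n", x$n_family))
  invisible(x)
}

.two_pool_moments <- function(structure, k_fast, k_slow, partition) {
  if (structure == "parallel") {
    c_fast <- partition / k_fast
    c_slow <- (1 - partition) / k_slow
    transit <- partition / k_fast + (1 - partition) / k_slow
    age_fast <- 1 / k_fast
    age_slow <- 1 / k_slow
    resp_slow <- 1 - partition
  } else {
    c_fast <- 1 / k_fast
    c_slow <- partition / k_slow
    transit <- 1 / k_fast + partition / k_slow
    age_fast <- 1 / k_fast
    age_slow <- 1 / k_fast + 1 / k_slow
    resp_slow <- partition
  }
  total <- c_fast + c_slow
  c(mass_frac_slow = c_slow / total,
    resp_frac_slow = resp_slow,
    mean_system_age = (c_fast * age_fast + c_slow * age_slow) / total,
    mean_transit_time = transit)
}

#' Mean system age and mean transit time of a fitted model
#'
#' For a one-pool model the mean age, transit time and turnover time all
#' equal \eqn{1/k}. For two-pool models the transit time is the flux-weighted
#' mean time to exit and the system age is the stock-weighted mean pool age
#' (parallel pools age as \eqn{1/k_i}; a series slow pool carries the fast
#' pool's residence on top of its own).
#'
#' @param fit a \code{"one_pool_fit"}, a \code{"two_pool_fit"}, or a list
#'   with \code{structure}, \code{k_fast}, \code{k_slow}, \code{partition}.
#'
#' @return Named numeric vector \code{c(mean_system_age = ,
#'   mean_transit_time = )} in years.
#' @examples
#' ages_and_transit(list(structure = "series", k_fast = 1 / 10,
#'                       k_slow = 1 / 1000, partition = 0.5))
#' @export
ages_and_transit <- function(fit) {
  if (inherits(fit, "one_pool_fit"))
    return(c(mean_system_age = fit$age_years,
             mean_transit_time = fit$age_years))
  need <- c("structure", "k_fast", "k_slow", "partition")
  if (!all(need %in% names(fit)))
    stop("fit must be a pool fit or carry ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- .two_pool_moments(fit$structure, fit$k_fast, fit$k_slow,
                         fit$partition)
  m[c("mean_system_age", "mean_transit_time")]
}
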