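# Piecewise (broken-line) regression with profiled breakpoint and AIC
# comparison against a simple linear model. The mean function is the
# continuous form y = b0 + b1 x + b2 (x - psi)_+ , so the two segments share
# the value at the breakpoint; psi is profiled over a deterministic grid of
# candidate values rather than iteratively linearized, which makes the fit
# reproducible and globally optimal on the grid.

.broken_rss <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

.profile_psi <- function(x, y, candidates) {
  rss <- vapply(candidates, function(p) .broken_rss(x, y, p), numeric(1))
  list(psi = candidates[which.min(rss)], rss = min(rss), all_rss = rss)
}

.psi_candidates <- function(x, edge_margin, min_side) {
  ux <- sort(unique(x))
  if (length(ux) < 4) return(numeric(0))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  rng <- range(x)
  lo <- rng[1] + edge_margin * diff(rng)
  hi <- rng[2] - edge_margin * diff(rng)
  mids <- mids[mids >= lo & mids <= hi]
  keep <- vapply(mids, function(p)
    sum(x < p) >= min_side && sum(x > p) >= min_side, logical(1))
  mids[keep]
}

#' Breakpoint (threshold) regression with AIC model comparison
#'
#' Fits the continuous broken-line model
#' \eqn{y = \beta_0 + \beta_1 x + \beta_2 (x - \psi)_+} by profiling the
#' breakpoint \eqn{\psi} over all midpoints between sorted unique predictor
#' values (excluding an edge margin), solving ordinary least squares at each
#' candidate, and returning the \eqn{\psi} with minimum residual sum of
#' squares. Both the piecewise and the simple linear model receive a
#' Gaussian-likelihood AIC, \eqn{n \ln(RSS/n) + 2p} with \eqn{p} = 4
#' (intercept, slope, slope change, breakpoint) and \eqn{p} = 2; a
#' breakpoint is only warranted when \code{delta_aic < 0}. The breakpoint
#' confidence interval comes from a seeded nonparametric pairs bootstrap.
#'
#' @param x predictor values (length >= 10, not constant).
#' @param y response values.
#' @param config an \code{\link{arid14c_config}} (edge margin, minimum
#'   points per side, bootstrap size, seed).
#' @param bootstrap compute the bootstrap CI? Skipping it makes repeated
#'   fits (e.g. simulation studies) much faster.
#' @param n_boot bootstrap resamples (default \code{config$bootstrap_n}).
#' @param seed bootstrap seed (default \code{config$seed}).
#'
#' @return An object of class \code{"breakpoint_fit"}: \code{psi},
#'   \code{intercept}, \code{slope_left}, \code{slope_right}, \code{r2},
#'   \code{aic_piecewise}, \code{aic_linear}, \code{delta_aic},
#'   \code{psi_ci} (2.5/97.5 percentiles, or NA without bootstrap),
#'   \code{n}, \code{candidates}.
#' @examples
#' set.seed(1)
#' x <- runif(80)
#' y <- ifelse(x > 0.6, 5 - 8 * (x - 0.6), 5) + rnorm(80, sd = 0.3)
#' fit <- fit_breakpoint(x, y, bootstrap = FALSE)
#' fit$psi
#' compare_aic(fit)
#' @export
fit_breakpoint <- function(x, y, config = arid14c_config(),
                           bootstrap = TRUE, n_boot = config$bootstrap_n,
                           seed = config$seed) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete observations", call. = FALSE)
  if (diff(range(x)) == 0) stop("x is constant", call. = FALSE)

  candidates <- .psi_candidates(x, config$breakpoint_edge_margin,
                                config$breakpoint_min_side)
  if (!length(candidates))
    stop("fewer than ", config$breakpoint_min_side,
         " points on either side of every candidate breakpoint",
         call. = FALSE)
  prof <- .profile_psi(x, y, candidates)
  psi <- prof$psi
  X <- cbind(1, x, pmax(x - psi, 0))
  beta <- stats::lm.fit(X, y)$coefficients
  rss_pw <- prof$rss
  lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(lin$residuals^2)
  tss <- sum((y - mean(y))^2)

  aic_pw <- n * log(rss_pw / n) + 2 * 4
  aic_lin <- n * log(rss_lin / n) + 2 * 2

  psi_ci <- c(NA_real_, NA_real_)
  if (bootstrap && n_boot > 0) {
    boot_psi <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        cb <- .psi_candidates(xb, config$breakpoint_edge_margin,
                              config$breakpoint_min_side)
        if (!length(cb)) return(NA_real_)
        .profile_psi(xb, yb, cb)$psi
      }, numeric(1))
    })
    psi_ci <- stats::quantile(boot_psi, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
  }

  structure(list(
    psi = psi, intercept = unname(beta[1]),
    slope_left = unname(beta[2]),
    slope_right = unname(beta[2] + beta[3]),
    r2 = 1 - rss_pw / tss,
    aic_piecewise = aic_pw, aic_linear = aic_lin,
    delta_aic = aic_pw - aic_lin,
    psi_ci = psi_ci, n = n, candidates = candidates,
    rss = rss_pw), class = "breakpoint_fit")
}

#' Preferred model from a breakpoint fit
#'
#' Returns \code{"piecewise"} when the broken-line model has the lower AIC
#' (\code{delta_aic < 0}); ties go to the simpler linear model.
#'
#' @param fit a \code{\link{fit_breakpoint}} result.
#' @return \code{"piecewise"} or \code{"linear"}.
#' @export
compare_aic <- function(fit) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  if (fit$delta_aic < 0) "piecewise" else "linear"
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Broken-line regression (n =", x$n, ")\n")
  cat(sprintf("  breakpoint psi = %.3f (95%% CI %.3f-%.3f)\n",
              x$psi, x$psi_ci[1], x$psi_ci[2]))
  cat(sprintf("  slopes %.2f -> %.2f, R2 = %.3f\n",
              x$slope_left, x$slope_right, x$r2))
  cat(sprintf("  delta AIC (piecewise - linear) = %.2f: %s preferred\n",
              x$delta_aic, compare_aic(x)))
  invisible(x)
}
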