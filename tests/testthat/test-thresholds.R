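piecewise_y <- function(x, psi, b0, b1, b2) b0 + b1 * x + b2 * pmax(x - psi, 0)

test_that("a noiseless breakpoint is recovered within one grid cell", {
  withr::with_seed(61, x <- runif(97, 0.46, 0.99))
  y <- piecewise_y(x, 0.87, -100, -50, -200)
  fit <- fit_breakpoint(x, y, bootstrap = FALSE)
  ux <- sort(unique(x))
  cell <- max(diff(ux[ux > 0.8 & ux < 0.95]))
  expect_lt(abs(fit$psi - 0.87), cell + 1e-12)
  # psi sits on the candidate grid, not exactly at 0.87, so the fitted
  # slopes carry the corresponding discretization error
  expect_equal(fit$slope_left, -50, tolerance = 0.02)
  expect_equal(fit$slope_right, -250, tolerance = 0.02)
  expect_gt(fit$r2, 0.999)
  expect_equal(compare_aic(fit), "piecewise")
})

test_that("strictly linear data prefer the linear model", {
  withr::with_seed(62, {
    x <- runif(100)
    y <- 2 + 3 * x + rnorm(100, 0, 1)
  })
  fit <- fit_breakpoint(x, y, bootstrap = FALSE)
  expect_gt(fit$delta_aic, 0)
  expect_equal(compare_aic(fit), "linear")
})

test_that("profiled OLS matches a normal-equations oracle", {
  withr::with_seed(63, {
    x <- runif(60); y <- rnorm(60)
  })
  psi <- 0.5
  X <- cbind(1, x, pmax(x - psi, 0))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  fit <- stats::lm.fit(X, y)
  expect_equal(unname(fit$coefficients), c(beta_oracle), tolerance = 1e-8)
  # and the returned psi attains the global grid minimum (exhaustive re-scan)
  y2 <- piecewise_y(x, 0.6, 0, 1, -4) + rnorm(60, 0, 0.2)
  bf <- fit_breakpoint(x, y2, bootstrap = FALSE)
  rss_all <- vapply(bf$candidates, function(p) {
    sum(stats::lm.fit(cbind(1, x, pmax(x - p, 0)), y2)$residuals^2)
  }, numeric(1))
  expect_equal(bf$rss, min(rss_all), tolerance = 1e-10)
  expect_equal(bf$psi, bf$candidates[which.min(rss_all)])
})

test_that("breakpoint recovery tightens as noise decreases", {
  spread <- vapply(c(50, 25, 10), function(sigma) {
    errs <- withr::with_seed(64, {
      vapply(1:40, function(r) {
        x <- runif(97, 0.46, 0.99)
        y <- piecewise_y(x, 0.87, -100, 0, -300) + rnorm(97, 0, sigma)
        abs(fit_breakpoint(x, y, bootstrap = FALSE)$psi - 0.87)
      }, numeric(1))
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(spread) <= 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_breakpoint(1:5, rnorm(5)), "at least 10")
  expect_error(fit_breakpoint(rep(1, 20), rnorm(20)), "constant")
  # clustered x: no candidate has 5 points on each side
  x <- c(rep(0, 12), rep(1, 3))
  expect_error(fit_breakpoint(x, rnorm(15), arid14c_config()), "side")
})

test_that("AIC tie-break favors the simpler model", {
  fit <- structure(list(delta_aic = 0), class = "breakpoint_fit")
  expect_equal(compare_aic(fit), "linear")
  fit$delta_aic <- -5
  expect_equal(compare_aic(fit), "piecewise")
})

test_that("the bootstrap CI is reproducible and brackets the estimate", {
  withr::with_seed(65, {
    x <- runif(97, 0.46, 0.99)
    y <- piecewise_y(x, 0.87, -100, 0, -300) + rnorm(97, 0, 20)
  })
  cfg <- arid14c_config(bootstrap_n = 99, seed = 7)
  f1 <- fit_breakpoint(x, y, cfg)
  f2 <- fit_breakpoint(x, y, cfg)
  expect_identical(f1$psi_ci, f2$psi_ci)
  expect_lte(f1$psi_ci[1], f1$psi)
  expect_gte(f1$psi_ci[2], f1$psi)
})
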