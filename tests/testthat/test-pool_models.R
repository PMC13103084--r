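test_that("flat-atmosphere pools sit at the closed-form steady state", {
  cv <- flat_curve()
  # F = k/(k + lambda); e.g. k = 1/1939 gives F ~ 0.81
  for (k in c(1 / 8267, 1 / 1939, 1 / 435, 1 / 50)) {
    f_expect <- k / (k + 1 / 8267)
    expect_equal(simulate_one_pool(k, cv, 2018),
                 fm_to_d14c(f_expect, 2018), tolerance = 1e-6)
  }
})

test_that("fast pools track the atmosphere and slow pools approach -1000", {
  cv <- default_curve
  expect_lt(abs(simulate_one_pool(1, cv, 2018) -
                  atm_delta14c(cv, 2018)), 15)
  d <- simulate_one_pool(c(1e-4, 1e-5), cv, 2018)
  expect_true(all(diff(d) < 0))
  expect_lt(d[2], -900)
  expect_error(simulate_one_pool(-1, cv, 2018), "> 0")
})

test_that("simulated Delta14C is monotone in k for old pools", {
  cv <- default_curve
  k <- 1 / seq(150, 6000, by = 50)
  d <- simulate_one_pool(k, cv, 2018)
  expect_true(all(diff(d) < 0))  # ages increasing -> Delta14C decreasing
})

test_that("flat-atmosphere fits recover the closed-form age", {
  cv <- flat_curve()
  for (f in c(0.5, 0.81, 0.95)) {
    obs <- fm_to_d14c(f, 2018)
    fit <- fit_one_pool(obs, cv, 2018)
    expect_equal(fit$age_years, 8267 * (1 - f) / f, tolerance = 0.005)
  }
})

test_that("one-pool fit round-trips a known rate", {
  cv <- default_curve
  obs <- simulate_one_pool(1 / 500, cv, 2018)
  fit <- fit_one_pool(obs, cv, 2018)
  expect_equal(fit$age_years, 500, tolerance = 1 / 500)
  expect_lt(abs(fit$residual), 0.1)
})

test_that("bomb-region observations yield two roots, longer transit kept", {
  cv <- default_curve
  fit <- fit_one_pool(50, cv, 2018)
  expect_equal(fit$n_solutions, 2)
  expect_equal(fit$selection, "longer_transit")
  expect_equal(fit$age_years, max(fit$all_ages))
  # both roots reproduce the observation
  for (a in fit$all_ages)
    expect_lt(abs(simulate_one_pool(1 / a, cv, 2018) - 50), 0.2)
  # an observation above the model maximum is out of range
  expect_error(fit_one_pool(150, cv, 2018), "outside model range")
})

test_that("two-pool degenerate reductions equal the one-pool model", {
  cv <- default_curve
  one <- simulate_one_pool(1 / 10, cv, 2018)
  par1 <- simulate_two_pool("parallel", 1 / 10, 1 / 5000, 1, cv, 2018)
  expect_identical(unname(par1[["bulk"]]), unname(one))
  expect_identical(unname(par1[["respired"]]), unname(one))
  ser0 <- simulate_two_pool("series", 1 / 10, 1 / 5000, 0, cv, 2018)
  expect_identical(unname(ser0[["bulk"]]), unname(one))
  expect_identical(unname(ser0[["respired"]]), unname(one))
})

test_that("parallel pools under a flat atmosphere match the mixture", {
  cv <- flat_curve()
  kf <- 1 / 10; ks <- 1 / 5000; g <- 0.9
  lam <- 1 / 8267
  ff <- kf / (kf + lam); fs <- ks / (ks + lam)
  cf <- g / kf; cs <- (1 - g) / ks
  out <- simulate_two_pool("parallel", kf, ks, g, cv, 2018)
  expect_equal(unname(out[["bulk"]]),
               fm_to_d14c((cf * ff + cs * fs) / (cf + cs), 2018),
               tolerance = 1e-6)
  expect_equal(unname(out[["respired"]]),
               fm_to_d14c(g * ff + (1 - g) * fs, 2018), tolerance = 1e-6)
})

test_that("two-pool parameter validation is enforced", {
  cv <- default_curve
  expect_error(simulate_two_pool("parallel", 1 / 500, 1 / 10, 0.5, cv,
                                 2018), "k_fast")
  expect_error(simulate_two_pool("parallel", 1 / 10, 1 / 500, 1.5, cv,
                                 2018), "partition")
})

test_that("two-pool fit recovers known parameters with k_fast fixed", {
  cv <- default_curve
  truth <- list(kf = 1 / 12, ks = 1 / 2500, g = 0.85)
  obs <- simulate_two_pool("parallel", truth$kf, truth$ks, truth$g, cv,
                           2018)
  cfg <- arid14c_config(k_fast_profile_grid = truth$kf)
  fit <- fit_two_pool(obs[["bulk"]], obs[["respired"]], "parallel", cv,
                      2018, cfg)
  expect_equal(fit$k_slow, truth$ks, tolerance = 0.01)
  expect_equal(fit$partition, truth$g, tolerance = 0.01)

  obs <- simulate_two_pool("series", truth$kf, truth$ks, 0.4, cv, 2018)
  fit <- fit_two_pool(obs[["bulk"]], obs[["respired"]], "series", cv,
                      2018, cfg)
  expect_equal(fit$k_slow, truth$ks, tolerance = 0.01)
  expect_equal(fit$partition, 0.4, tolerance = 0.01)
})

test_that("equal bulk and respired observations collapse to one pool", {
  cv <- default_curve
  obs <- simulate_one_pool(1 / 800, cv, 2018)
  fit <- fit_two_pool(obs, obs, "parallel", cv, 2018)
  # the fitted mixture must put essentially all flux and stock at one rate
  expect_lt(max(abs(fit$residuals)), 1)
  expect_true(fit$partition < 0.05 || fit$partition > 0.95 ||
                fit$k_fast / fit$k_slow < 1.5)
})

test_that("ages and transit times follow the compartmental formulas", {
  expect_equal(ages_and_transit(list(structure = "parallel",
                                     k_fast = 1 / 10, k_slow = 1 / 5000,
                                     partition = 1)),
               c(mean_system_age = 10, mean_transit_time = 10))
  at <- ages_and_transit(list(structure = "series", k_fast = 1 / 10,
                              k_slow = 1 / 1000, partition = 0.5))
  expect_equal(unname(at["mean_transit_time"]), 10 + 500)
  # system age: stock-weighted pool ages
  cf <- 10; cs <- 0.5 * 1000
  expect_equal(unname(at["mean_system_age"]),
               (cf * 10 + cs * (10 + 1000)) / (cf + cs))
})

test_that("series system age matches a stochastic particle oracle", {
  kf <- 1 / 10; ks <- 1 / 1000; a21 <- 0.5
  withr::with_seed(55, {
    n <- 2e5
    # stationary-mass sampling: pool membership by stock share, then the
    # within-pool age (slow-pool atoms carry their fast-pool residence)
    cf <- 1 / kf; cs <- a21 / ks
    in_slow <- runif(n) < cs / (cf + cs)
    age <- ifelse(in_slow,
                  rexp(n, kf) + rexp(n, ks),
                  rexp(n, kf))
    mc <- mean(age)
  })
  at <- ages_and_transit(list(structure = "series", k_fast = kf,
                              k_slow = ks, partition = a21))
  expect_equal(unname(at["mean_system_age"]), mc, tolerance = 0.02)
})

test_that("one-pool age equals transit equals turnover", {
  cv <- default_curve
  obs <- simulate_one_pool(1 / 520, cv, 2018)
  fit <- fit_one_pool(obs, cv, 2018)
  at <- ages_and_transit(fit)
  expect_equal(unname(at["mean_system_age"]),
               unname(at["mean_transit_time"]))
  expect_equal(unname(at["mean_system_age"]), 520, tolerance = 0.01)
})

test_that("one-pool parameter recovery under 2 permil noise", {
  cv <- default_curve
  withr::with_seed(56, {
    ages <- exp(runif(50, log(50), log(5000)))
    noise <- rnorm(50, 0, 2)
  })
  err <- vapply(seq_along(ages), function(i) {
    obs <- simulate_one_pool(1 / ages[i], cv, 2018) + noise[i]
    fit <- try(fit_one_pool(obs, cv, 2018), silent = TRUE)
    if (inherits(fit, "try-error")) return(Inf)  # pushed out of range
    abs(fit$age_years - ages[i]) / ages[i]
  }, numeric(1))
  expect_lt(median(err), 0.05)
})
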