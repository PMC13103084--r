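test_that("calcite-CO2 equilibrium offset is applied", {
  expect_equal(sic_equilibrium_d13c(0), -9.6)
  expect_equal(sic_equilibrium_d13c(9.6), 0)
  expect_equal(sic_equilibrium_d13c(-5), -14.6)
  expect_error(sic_equilibrium_d13c(NA), "finite")
})

test_that("delta13C mixing recovers the carbonate share", {
  p <- f_sic_from_d13c(-20, -8, -24)
  expect_equal(p$f_sic, 0.25)
  expect_equal(p$f_soc, 0.75)
  expect_false(p$clamped)
  expect_equal(f_sic_from_d13c(-24, -8, -24)$f_sic, 0)
  expect_error(f_sic_from_d13c(-20, -24, -24), "unidentifiable")
  # out-of-simplex estimates are clamped and flagged
  p <- f_sic_from_d13c(-25, -8, -24)
  expect_equal(p$f_sic, 0)
  expect_true(p$clamped)
})

test_that("composed delta13C mixtures round-trip to 1e-9", {
  withr::with_seed(31, {
    for (i in 1:50) {
      d_soc <- rnorm(1, -24, 2)
      d_eq <- rnorm(1, -9.6, 2)
      if (abs(d_eq - d_soc) < 2.5) next
      f <- runif(1)
      mix <- f * d_eq + (1 - f) * d_soc
      expect_equal(f_sic_from_d13c(mix, d_eq, d_soc)$f_sic, f,
                   tolerance = 1e-9)
    }
  })
})

test_that("Delta14C adjustment inverts the carbonate mixing exactly", {
  expect_equal(adjust_delta14c_for_sic(-100, 0.25, -600), 200 / 3,
               tolerance = 1e-12)
  expect_equal(adjust_delta14c_for_sic(-50, 0, -1000), -50)
  # fixed point: CO2 already at the carbonate signature stays put
  expect_equal(adjust_delta14c_for_sic(-600, 0.4, -600), -600)
  expect_error(adjust_delta14c_for_sic(-100, 1, -1000), "no SOC")
  withr::with_seed(32, {
    for (i in 1:50) {
      soc <- runif(1, -500, 100); sic <- runif(1, -1000, -200)
      f <- runif(1, 0, 0.95)
      mix <- f * sic + (1 - f) * soc
      expect_equal(adjust_delta14c_for_sic(mix, f, sic), soc,
                   tolerance = 1e-9)
    }
  })
})

test_that("screening applies the floor, exclusion cut and region rules", {
  expect_equal(screen_site(0.05, NA), "assumed_zero_sic")
  expect_equal(screen_site(1.0, 0.20), "excluded_high_fsic")
  expect_equal(screen_site(1.0, 0.10), "included_original")
  expect_equal(screen_site(1.0, 0.15), "included_original")  # cut is strict
  cfg <- arid14c_config(excluded_regions = "China Loess Plateau")
  expect_equal(screen_site(1.0, 0.10, "China Loess Plateau", cfg),
               "excluded_region")
  # high f_SIC takes precedence over the region rule
  expect_equal(screen_site(1.0, 0.30, "China Loess Plateau", cfg),
               "excluded_high_fsic")
  expect_error(screen_site(-1, 0.1), "non-negative")
})

test_that("every generated site gets exactly one screening status", {
  sites <- generate_sites(scenario_config(seed = 5))
  part <- sic_partition(sites$d13c_co2, sites$d13c_soc, sites$d13c_sic,
                        sites$sic, sites$delta14c_co2, sites$region)
  expect_equal(nrow(part), 97)
  expect_true(all(part$status %in% c("assumed_zero_sic",
                                     "included_original",
                                     "excluded_high_fsic",
                                     "excluded_region")))
  expect_equal(part$f_sic + part$f_soc, rep(1, 97))
  expect_true(all(part$f_sic[part$status == "assumed_zero_sic"] == 0))
  expect_true(all(part$f_sic[part$status == "excluded_high_fsic"] > 0.15))
  # every status is exercised at the default carbonate prevalence
  expect_gt(sum(part$status == "assumed_zero_sic"), 25)
  expect_gt(sum(part$status == "excluded_high_fsic"), 3)
  expect_gt(sum(part$status == "included_original"), 20)
})
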