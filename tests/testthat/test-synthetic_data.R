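test_that("generation is deterministic given the seed", {
  s1 <- generate_sites(scenario_config(n_sites = 20, seed = 9))
  s2 <- generate_sites(scenario_config(n_sites = 20, seed = 9))
  expect_identical(s1, s2)
  s3 <- generate_sites(scenario_config(n_sites = 20, seed = 10))
  expect_false(identical(s1$delta14c_bulk, s3$delta14c_bulk))
})

test_that("covariates respect configured ranges across seeds", {
  for (seed in 1:20) {
    s <- generate_sites(scenario_config(n_sites = 30, seed = seed))
    expect_true(all(s$aridity >= 0.46 & s$aridity <= 0.99))
    expect_true(all(s$mat >= -3.4 & s$mat <= 24.0))
    expect_true(all(s$sampling_year %in% 2015:2020))
    expect_true(all(s$soc > 0))
    expect_true(all(s$delta14c_bulk >= -1000 & s$delta14c_co2 >= -1000))
  }
})

test_that("the emitted table matches the pipeline schema", {
  s <- generate_sites(scenario_config(n_sites = 15, seed = 2))
  expect_silent(validate_sites(s))
  expect_equal(nrow(s), 15)
  tr <- attr(s, "truth")
  expect_equal(tr$site_id, s$site_id)
  expect_true(all(c("age_bulk_true", "k_resp_true", "f_sic_true",
                    "f_old_true") %in% names(tr)))
})

test_that("noiseless sites are exactly invertible", {
  cfg <- scenario_config(n_sites = 12, seed = 3, noise_delta14c = 0,
                         noise_d13c = 0)
  s <- generate_sites(cfg)
  tr <- attr(s, "truth")
  cv <- synthetic_bomb_curve()
  for (i in seq_len(6)) {
    fit <- fit_one_pool(s$delta14c_bulk[i], cv, s$sampling_year[i])
    expect_lt(abs(fit$age_years - tr$age_bulk_true[i]), 1)
  }
  # delta13C partition recovers the true carbonate share where SIC > floor
  j <- which(s$sic >= 0.1)
  if (length(j)) {
    eq <- sic_equilibrium_d13c(s$d13c_sic[j])
    got <- f_sic_from_d13c(s$d13c_co2[j], eq, s$d13c_soc[j])$f_sic
    expect_equal(got, tr$f_sic_true[j], tolerance = 1e-9)
  }
})

test_that("carbonate prevalence mirrors the zero-inflated design", {
  n_zero <- vapply(1:10, function(seed) {
    sum(generate_sites(scenario_config(seed = seed))$sic < 0.1)
  }, numeric(1))
  expect_gt(mean(n_zero), 35)   # about 45/97 on average
  expect_lt(mean(n_zero), 55)
  s <- generate_sites(scenario_config(seed = 1))
  expect_equal(sum(!is.na(s$w_maoc)), 41)
  j <- !is.na(s$w_maoc)
  expect_equal(s$w_poc[j] + s$w_maoc[j], rep(1, 41))
})

test_that("the embedded aridity breakpoint is recoverable", {
  hits <- vapply(1:100, function(seed) {
    s <- generate_sites(scenario_config(seed = seed))
    fit <- fit_breakpoint(s$aridity, s$delta14c_bulk,
                          arid14c_config(bootstrap_n = 199, seed = seed))
    fit$psi_ci[1] <= 0.87 && fit$psi_ci[2] >= 0.87
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("incubation gate needs both the 1% and the 0.2 mg condition", {
  expect_true(incubation_gate(2.0, 150))
  expect_false(incubation_gate(0.1, 5))    # fails the 0.2 mg floor
  expect_false(incubation_gate(0.25, 50))  # 0.5% of total C < 1%
  expect_true(incubation_gate(0.2, 20))    # both conditions at the edge
  expect_error(incubation_gate(-1, 10), "non-negative")
})

test_that("write_sites emits the table and a truth sidecar", {
  s <- generate_sites(scenario_config(n_sites = 12, seed = 4))
  path <- file.path(withr::local_tempdir(), "sites.csv")
  truth_path <- write_sites(s, path)
  back <- read_sites(path)
  expect_equal(back$site_id, s$site_id)
  expect_equal(back$delta14c_bulk, s$delta14c_bulk, tolerance = 1e-9)
  tr <- utils::read.csv(truth_path)
  expect_equal(nrow(tr), 12)
})
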