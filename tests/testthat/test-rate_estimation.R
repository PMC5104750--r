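test_that("delta13C-DIC converts to absolute 13C-DIC concentration", {
  expect_equal(dic13_concentration(0, 0), 0)
  # frozen: 7400 uM x 0.0111796 / 1.0111796
  expect_equal(dic13_concentration(0, 7.4), 81.814387869375529, tolerance = 1e-10)
  d <- seq(-50, 500, length.out = 100)
  expect_true(all(diff(dic13_concentration(d, 7.4)) > 0))
})

test_that("excess time series is anchored at the t = 0 baseline", {
  s <- incubation_series(c(0, 6, 12, 24, 48), rep(-10, 5))
  ex <- excess_timeseries(s)
  expect_equal(ex$excess_13c_uM, rep(0, 5))
  expect_error(incubation_series(c(6, 12, 24), c(-10, -9, -8)),
               "missing baseline")
  # forward construction: add k uM of 13C-DIC per hour, recover k t exactly
  k <- 0.11
  t <- c(0, 6, 12, 24, 48)
  c13 <- dic13_concentration(-10, 7.4) + k * t
  delta <- atom_fraction_to_delta(c13 / 7400)
  ex2 <- excess_timeseries(incubation_series(t, delta))
  expect_equal(ex2$excess_13c_uM, k * t, tolerance = 1e-8)
})

test_that("fit_rate recovers noise-free rates and flags plateaus", {
  s <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
                                               plateau_h = 12,
                                               noise_sd_permil = 0))[[1]]
  est <- fit_rate(s)
  expect_equal(est$rate_uM_d, 2.6, tolerance = 1e-8)
  expect_lt(est$stderr_uM_d, 1e-8)
  expect_true(est$plateau_detected)
  expect_equal(est$total_turnover_uM, 2.6 / 24 * 12, tolerance = 1e-8)
  # zero activity
  s0 <- generate_incubation(incubation_scenario(true_rate_uM_d = 0,
                                                noise_sd_permil = 0))[[1]]
  expect_equal(fit_rate(s0)$rate_uM_d, 0, tolerance = 1e-10)
  # no plateau when the trajectory stays linear to 48 h
  slin <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
                                                  plateau_h = 48,
                                                  noise_sd_permil = 0))[[1]]
  elin <- fit_rate(slin)
  expect_equal(elin$rate_uM_d, 2.6, tolerance = 1e-8)
  expect_false(elin$plateau_detected)
  expect_error(fit_rate(s, window = c(0, 3)), "insufficient data")
})

test_that("rate is invariant to a constant delta baseline offset", {
  s <- generate_incubation(incubation_scenario(seed = 7))[[1]]
  base <- fit_rate(s)$rate_uM_d
  for (off in c(-20, 5, 15)) {
    c13 <- dic13_concentration(s$delta_dic, s$ambient_dic_mM)
    c13_off <- c13 + dic13_concentration(off, s$ambient_dic_mM) -
      dic13_concentration(0, s$ambient_dic_mM)
    shifted <- incubation_series(s$time_h,
                                 atom_fraction_to_delta(c13_off / (s$ambient_dic_mM * 1000)),
                                 ambient_dic_mM = s$ambient_dic_mM)
    expect_equal(fit_rate(shifted)$rate_uM_d, base, tolerance = 1e-6)
  }
})

test_that("estimator is unbiased to <= 5% at the method's delta noise", {
  rates <- c(0.1, 0.7, 2.6, 5)
  for (r in rates) {
    est <- vapply(1:200, function(i) {
      s <- generate_incubation(incubation_scenario(true_rate_uM_d = r,
                                                   noise_sd_permil = 0.1,
                                                   seed = i))[[1]]
      fit_rate(s)$rate_uM_d
    }, numeric(1))
    expect_lt(abs(mean(est) - r) / r, 0.05)
  }
})

test_that("turnover/rate consistency breaks only when a plateau is flagged", {
  set.seed(5)
  for (i in 1:20) {
    r <- runif(1, 0.5, 4)
    plateau <- sample(c(12, 24, 48), 1)
    s <- generate_incubation(incubation_scenario(true_rate_uM_d = r,
                                                 plateau_h = plateau,
                                                 noise_sd_permil = 0))[[1]]
    est <- fit_rate(s)
    window_yield <- est$rate_uM_d * 12 / 24
    if (!isTRUE(est$plateau_detected))
      expect_gte(est$total_turnover_uM + 1e-9, window_yield)
  }
})

test_that("compare_treatments tabulates and preserves effect ratios", {
  e1 <- fit_rate(generate_incubation(incubation_scenario(
    true_rate_uM_d = 1.5, treatment = "dark", noise_sd_permil = 0))[[1]])
  expect_equal(nrow(compare_treatments(list(e1))), 1L)
  # oxygen amendment constructed with doubled turnover (plateau 24 h vs 12 h)
  e2 <- fit_rate(generate_incubation(incubation_scenario(
    true_rate_uM_d = 1.5, treatment = "oxygen", plateau_h = 24,
    noise_sd_permil = 0))[[1]])
  tab <- compare_treatments(list(e1, e2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$total_turnover_uM[tab$treatment == "oxygen"] /
                 tab$total_turnover_uM[tab$treatment == "dark"], 2,
               tolerance = 1e-8)
  expect_equal(tab$rate_uM_d[1], tab$rate_uM_d[2], tolerance = 1e-8)
})

test_that("incubation tables round-trip through the CSV layout", {
  series <- c(
    generate_incubation(incubation_scenario(depth_m = 14, treatment = "dark", seed = 2)),
    generate_incubation(incubation_scenario(depth_m = 16, treatment = "nitrate", seed = 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_incubations(series, path)
  back <- read_incubations(path)
  expect_length(back, 2L)
  depths <- unname(sort(vapply(back, `[[`, numeric(1), "depth_m")))
  expect_equal(depths, c(14, 16))
  s16 <- back[[which(vapply(back, `[[`, numeric(1), "depth_m") == 16)]]
  orig <- series[[2]]
  expect_equal(s16$delta_dic, orig$delta_dic, tolerance = 1e-6)
})
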