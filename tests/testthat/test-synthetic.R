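# independent tridiagonal (Thomas) solver used as the fine-grid oracle; a
# deliberately separate implementation from the package's dense solve
thomas_solve <- function(a, b, cc, d) {
  n <- length(d)
  for (i in 2:n) {
    w <- a[i] / b[i - 1L]
    b[i] <- b[i] - w * cc[i - 1L]
    d[i] <- d[i] - w * d[i - 1L]
  }
  x <- numeric(n)
  x[n] <- d[n] / b[n]
  for (i in (n - 1L):1L) x[i] <- (d[i] - cc[i] * x[i + 1L]) / b[i]
  x
}

oracle_column_d13c <- function(h, z_query, k = 0.06, alpha = 1.005) {
  z <- seq(0, 21, by = h)
  n <- length(z)
  kz <- 4e-3 * 8.64
  kk <- ifelse(z >= 12 & z <= 16, k, 0)
  solve1 <- function(kvec, ctop, cbot) {
    a <- rep(kz / h^2, n); b <- rep(-2 * kz / h^2, n) - kvec
    cc <- rep(kz / h^2, n); d <- rep(0, n)
    a[1] <- 0; b[1] <- 1; cc[1] <- 0; d[1] <- ctop
    a[n] <- 0; b[n] <- 1; cc[n] <- 0; d[n] <- cbot
    thomas_solve(a, b, cc, d)
  }
  fb <- delta_to_atom_fraction(-50)
  fs <- delta_to_atom_fraction(-47)
  c12 <- solve1(kk, 0.003 * (1 - fs), 2200 * (1 - fb))
  c13 <- solve1(kk / alpha, 0.003 * fs, 2200 * fb)
  i <- which.min(abs(z - z_query))
  ratio_to_delta(c13[i] / c12[i])
}

test_that("column generator is deterministic given (scenario, seed)", {
  a <- generate_column(column_scenario(seed = 42))
  b <- generate_column(column_scenario(seed = 42))
  expect_identical(a, b)
  c_ <- generate_column(column_scenario(seed = 43))
  expect_false(identical(a$ch4_uM, c_$ch4_uM))
})

test_that("diffusion-only column is linear with invariant delta and no oxidation zone", {
  sc <- column_scenario(seed = 1, k_d = 0)
  pr <- generate_column(sc, add_noise = FALSE)
  # linear CH4 between boundaries
  fit <- lm(ch4_uM ~ depth_m, data = pr)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
  # delta varies only between the two boundary compositions
  expect_lt(diff(range(pr$d13c_ch4_permil)), 3.1)
  zones <- classify_ch4_zones(pr)
  expect_false("oxidation" %in% zones$zone)
})

test_that("two-isotope solve matches an independent fine-grid oracle to 0.05 permil", {
  sc <- column_scenario(seed = 1, depth_grid_m = seq(0, 21, by = 0.01))
  pr <- generate_column(sc, add_noise = FALSE)
  d_pkg <- pr$d13c_ch4_permil[which.min(abs(pr$depth_m - 12))]
  d_oracle <- oracle_column_d13c(h = 0.001, z_query = 12)
  expect_lt(abs(d_pkg - d_oracle), 0.05)
})

test_that("solver conserves mass: flux divergence equals reaction sink", {
  for (k in c(0.03, 0.06, 0.3)) {
    pr <- generate_column(column_scenario(seed = 1, k_d = k), add_noise = FALSE)
    bal <- attr(pr, "balance")
    expect_lt(bal$rel_error, 0.001)
    expect_gt(bal$reaction_sink, 0)
  }
})

test_that("closed-form mode round-trips the Rayleigh fit exactly", {
  pr <- generate_column(column_scenario(seed = 1), mode = "closed_form",
                        add_noise = FALSE)
  inz <- pr$depth_m >= 12 & pr$depth_m <= 16
  c_ref <- pr$ch4_uM[which.min(abs(pr$depth_m - 16))]
  f <- pmin(pr$ch4_uM[inz] / c_ref, 1)
  fit <- rayleigh_fit_alpha(f, pr$d13c_ch4_permil[inz], delta0 = -50)
  expect_equal(fit$alpha, 1.005, tolerance = 1e-9)
})

test_that("mechanistic profiles under-express the intrinsic fractionation", {
  # steady-state reaction-diffusion expresses roughly half the intrinsic
  # epsilon (apparent 1/alpha - 1 approaches sqrt(1/alpha) - 1 in the
  # reaction-dominated regime), unlike the closed-system batch model
  pr <- generate_column(column_scenario(seed = 1, k_d = 0.3), add_noise = FALSE)
  inz <- pr$depth_m >= 12 & pr$depth_m <= 16
  c_ref <- pr$ch4_uM[which.min(abs(pr$depth_m - 16))]
  d0 <- pr$d13c_ch4_permil[which.min(abs(pr$depth_m - 16))]
  fit <- rayleigh_fit_alpha(pmin(pr$ch4_uM[inz] / c_ref, 1),
                            pr$d13c_ch4_permil[inz], delta0 = d0)
  eps_intrinsic <- (1 / 1.005 - 1) * 1000
  ratio <- fit$epsilon / eps_intrinsic
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.6)
})

test_that("incubation generator round-trips through the rate estimator", {
  # zero rate: delta constant (up to nothing, with noise off)
  s0 <- generate_incubation(incubation_scenario(true_rate_uM_d = 0,
                                                noise_sd_permil = 0))[[1]]
  expect_equal(diff(range(s0$delta_dic)), 0, tolerance = 1e-12)
  # noise-free 2.6 uM/d with 12 h plateau: exact recovery, plateau flagged
  s <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
                                               plateau_h = 12,
                                               noise_sd_permil = 0))[[1]]
  est <- fit_rate(s)
  expect_equal(est$rate_uM_d, 2.6, tolerance = 1e-8)
  expect_true(est$plateau_detected)
  # exponential substrate-exhaustion mode slows instead of stopping dead
  se <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
                                                plateau_h = 12,
                                                kinetics = "exponential",
                                                noise_sd_permil = 0))[[1]]
  exc <- excess_timeseries(se)$excess_13c_uM
  expect_true(all(diff(exc) > 0))                 # never fully flat
  expect_lt(exc[5], 2.6 / 24 * 48)                # but sub-linear
})

test_that("incubation generator is seed-reproducible with derived substreams", {
  a <- generate_incubation(incubation_scenario(seed = 9, replicates = 3))
  b <- generate_incubation(incubation_scenario(seed = 9, replicates = 3))
  expect_identical(a, b)
  expect_false(identical(a[[1]]$delta_dic, a[[2]]$delta_dic))
})

test_that("mean recovered rate is within 5% of truth over 200 noisy replicates", {
  est <- vapply(1:200, function(i) {
    s <- generate_incubation(incubation_scenario(true_rate_uM_d = 2.6,
                                                 noise_sd_permil = 0.1,
                                                 seed = i))[[1]]
    fit_rate(s)$rate_uM_d
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.6) / 2.6, 0.05)
})
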