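# brute-force oracle: OLS slope in every contiguous window, pick max |slope|
brute_force_steepest <- function(z, c_, w) {
  best <- NULL
  for (i in seq_len(length(z) - w + 1L)) {
    idx <- i:(i + w - 1L)
    slope <- unname(coef(lm(c_[idx] ~ z[idx]))[2L])
    if (is.null(best) || abs(slope) > abs(best$slope) + 1e-15)
      best <- list(slope = slope, window = range(z[idx]))
  }
  best
}

test_that("steepest_gradient matches exhaustive window search", {
  z <- seq(10, 18, by = 0.5)
  # piecewise profile with a known steep segment at 13-14.5 m
  c_ <- ifelse(z < 13, 260, ifelse(z < 14.5, 260 - 170 * (z - 13), 5))
  pr <- data.frame(depth_m = z, o2_uM = c_)
  for (w in c(3, 4, 5)) {
    g <- steepest_gradient(pr, "o2_uM", w)
    oracle <- brute_force_steepest(z, c_, w)
    expect_equal(g$slope_uM_m, oracle$slope, tolerance = 1e-12)
    expect_equal(g$depth_window, oracle$window)
  }
  expect_gte(g$depth_window[1], 12.5)   # bracket the steep segment
  expect_lte(g$depth_window[2], 15)
  # randomized profiles against the oracle
  set.seed(41)
  for (i in 1:10) {
    cr <- cumsum(rnorm(length(z)))
    pr2 <- data.frame(depth_m = z, x = cr)
    g2 <- steepest_gradient(pr2, "x", 3)
    o2 <- brute_force_steepest(z, cr, 3)
    expect_equal(g2$slope_uM_m, o2$slope, tolerance = 1e-12)
  }
})

test_that("steepest_gradient handles linear, flat and degenerate input", {
  z <- seq(0, 10, by = 1)
  lin <- data.frame(depth_m = z, a = 5 - 2 * z)
  g <- steepest_gradient(lin, "a", 4)
  expect_equal(g$slope_uM_m, -2, tolerance = 1e-12)
  flat <- data.frame(depth_m = z, a = rep(3, length(z)))
  expect_equal(steepest_gradient(flat, "a", 3)$slope_uM_m, 0, tolerance = 1e-12)
  expect_error(steepest_gradient(lin[1:2, ], "a", 3), "insufficient data")
  expect_error(steepest_gradient(lin, "nope", 3), "missing analyte")
})

test_that("diffusive flux applies Fick's law with the cm2/s -> m2/d conversion", {
  g0 <- list(slope_uM_m = 0, stderr_uM_m = 0)
  expect_equal(diffusive_flux(g0)$flux_mmol_m2_d, 0)
  # hand unit-conversion oracle: 4e-3 cm2/s = 0.03456 m2/d
  g <- list(slope_uM_m = -289.35, stderr_uM_m = 10)
  fl <- diffusive_flux(g, 4e-3)
  expect_equal(fl$flux_mmol_m2_d, 9.999936, tolerance = 1e-9)
  expect_equal(fl$stderr_mmol_m2_d, 0.3456, tolerance = 1e-9)
  # linear in Kz
  expect_equal(diffusive_flux(g, 8e-3)$flux_mmol_m2_d,
               2 * fl$flux_mmol_m2_d, tolerance = 1e-12)
  # orientation: concentration increasing with depth -> upward (negative) flux
  up <- diffusive_flux(list(slope_uM_m = 50, stderr_uM_m = 0))
  expect_lt(up$flux_mmol_m2_d, 0)
})

test_that("diffusive flux of a steady no-reaction profile equals the boundary-difference flux", {
  # linear profile between fixed boundaries: J = -Kz (C2 - C1)/(z2 - z1)
  z <- seq(16, 19, by = 0.25)
  c1 <- 50; c2 <- 2200
  pr <- data.frame(depth_m = z, ch4_uM = c1 + (c2 - c1) * (z - 16) / 3)
  g <- steepest_gradient(pr, "ch4_uM", 5)
  fl <- diffusive_flux(g, 4e-3)
  analytic <- -4e-3 * 8.64 * (c2 - c1) / 3
  expect_equal(fl$flux_mmol_m2_d, analytic, tolerance = 1e-9)
})

test_that("electron capacities convert molar to electron-equivalent fluxes", {
  tab <- electron_capacity_table()
  ef <- electron_flux(-1.3875, "CH4", tab)
  expect_equal(ef$e_flux_mmol_m2_d, -11.1, tolerance = 1e-9)
  expect_equal(ef$role, "donor")
  expect_equal(electron_flux(0, "O2", tab)$e_flux_mmol_m2_d, 0)
  expect_equal(electron_flux(-0.42, "Fe2", tab)$e_flux_mmol_m2_d, -0.42)
  expect_error(electron_flux(1, "Xe", tab), "missing electron capacity")
  # overriding a capacity row replaces the default entry
  tab2 <- electron_capacity_table(data.frame(
    species = "NO3", half_reaction = "NO3 -> N2", electrons = 5L,
    role = "acceptor", default = TRUE))
  expect_equal(capacity <- tab2$electrons[tab2$species == "NO3" & tab2$default], 5L)
})

test_that("budget reproduces printed electron-flux arithmetic after report rounding", {
  eb <- budget(data.frame(
    species = c("O2", "NO3", "SO4", "CH4", "Fe2", "NH4"),
    role = c("acceptor", "acceptor", "acceptor", "donor", "donor", "donor"),
    e_flux_mmol_m2_d = c(7.3, 0.15, 0.01, -11.1, -0.03, -1.7),
    stderr_mmol_m2_d = c(0.03, 0.02, 0.09, 2.0, 0.01, 0.45)))
  rep_ <- budget_report(eb)
  expect_equal(rep_$e_flux_mmol_m2_d[rep_$species == "Sum" & rep_$role == "acceptor"], 7.5)
  expect_equal(rep_$e_flux_mmol_m2_d[rep_$species == "Sum" & rep_$role == "donor"], -12.8)
  expect_equal(rep_$e_flux_mmol_m2_d[rep_$species == "Deficit"], 5.3)
  expect_equal(eb$deficit, 5.37, tolerance = 1e-12)        # full precision kept
  expect_error(budget(data.frame(species = "O2", role = "acceptor",
                                 e_flux_mmol_m2_d = 7.3)),
               "incomplete budget")
})

test_that("budget is permutation-invariant and additive under flux splitting", {
  df <- data.frame(
    species = c("O2", "NO3", "CH4", "NH4"),
    role = c("acceptor", "acceptor", "donor", "donor"),
    e_flux_mmol_m2_d = c(7.3, 0.15, -11.1, -1.7),
    stderr_mmol_m2_d = c(0.03, 0.02, 2.0, 0.45))
  base <- budget(df)
  perm <- budget(df[c(3, 1, 4, 2), ])
  expect_equal(perm$acceptor_sum, base$acceptor_sum)
  expect_equal(perm$donor_sum, base$donor_sum)
  expect_equal(perm$deficit, base$deficit)
  split <- rbind(df[df$species != "CH4", ],
                 data.frame(species = c("CH4a", "CH4b"), role = "donor",
                            e_flux_mmol_m2_d = c(-5, -6.1),
                            stderr_mmol_m2_d = c(0, 0)))
  expect_equal(budget(split)$donor_sum, base$donor_sum)
  expect_equal(budget(split)$acceptor_sum, base$acceptor_sum)
})

test_that("quadrature propagation agrees with Monte-Carlo to <= 2%", {
  sds <- c(0.03, 0.02, 0.09, 2.0, 0.01, 0.45)
  eb <- budget(data.frame(
    species = c("O2", "NO3", "SO4", "CH4", "Fe2", "NH4"),
    role = c("acceptor", "acceptor", "acceptor", "donor", "donor", "donor"),
    e_flux_mmol_m2_d = c(7.3, 0.15, 0.01, -11.1, -0.03, -1.7),
    stderr_mmol_m2_d = sds))
  set.seed(99)
  n <- 1e5
  draws <- matrix(rnorm(6 * n, 0, rep(sds, each = n)), nrow = n)
  mc_acc <- sd(rowSums(draws[, 1:3]))
  mc_don <- sd(rowSums(draws[, 4:6]))
  mc_def <- sd(rowSums(draws))
  expect_lt(abs(eb$acceptor_sd - mc_acc) / mc_acc, 0.02)
  expect_lt(abs(eb$donor_sd - mc_don) / mc_don, 0.02)
  expect_lt(abs(eb$deficit_sd - mc_def) / mc_def, 0.02)
})

test_that("oxidant:methane stoichiometric ratios follow the half-reactions", {
  expect_equal(oxidant_ratio("NO3", oxidant_half_reaction = "NO3 -> NO2"), 4)
  expect_equal(oxidant_ratio("NO2"), 8 / 3)
  expect_equal(oxidant_ratio("O2"), 2)
  # budget-default nitrate half-reaction (to N2) gives 8/5 instead
  expect_equal(oxidant_ratio("NO3"), 8 / 5)
  expect_error(oxidant_ratio("NO3", oxidant_half_reaction = "NO3 -> NH4"),
               "no entry")
})
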