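test_that("sigma0 matches the published equation-of-state check values", {
  # One-atmosphere density check values (S, T, expected rho, kg m-3)
  expect_equal(potential_density_anomaly(5, 0, 0, -60) + 1000,
               999.96675, tolerance = 1e-8)
  expect_equal(potential_density_anomaly(5, 35, 0, -60) + 1000,
               1027.67547, tolerance = 1e-8)
  expect_equal(potential_density_anomaly(25, 35, 0, -60) + 1000,
               1023.34306, tolerance = 1e-8)
  # adiabatic gradient and potential temperature check values
  expect_equal(phytofate:::adiabatic_gradient(40, 40, 10000),
               3.255976e-4, tolerance = 1e-6)
  expect_equal(phytofate:::potential_temperature(40, 40, 10000, 0),
               36.89073, tolerance = 1e-6)
})

test_that("sigma0 is uniform for uniform water and increases with S", {
  sig <- potential_density_anomaly(rep(-1, 5), rep(34.2, 5),
                                   c(0, 10, 20, 30, 40), -62)
  expect_lt(diff(range(sig)), 1e-3)  # only the tiny pressure correction
  s_grid <- seq(30, 36, 0.5)
  sig_s <- potential_density_anomaly(rep(0, length(s_grid)), s_grid,
                                     rep(0, length(s_grid)), -62)
  expect_true(all(diff(sig_s) > 0))
  expect_error(potential_density_anomaly(-5, 34, 0, -62), "oceanic range")
})

test_that("mixed-layer depth finds a density step and flags no-crossing", {
  depth <- 0:200
  # threshold reached exactly at 50 m on a ramp: unambiguous crossing
  ramp <- 27 + pmax(0, depth - 40) * 0.001
  expect_equal(as.numeric(mixed_layer_depth(ramp, depth)), 50,
               tolerance = 1e-9)
  # a discrete step between 49 and 50 m localizes within the bracket
  sig <- ifelse(depth < 50, 27, 27.5)
  step_mld <- as.numeric(mixed_layer_depth(sig, depth))
  expect_gte(step_mld, 49); expect_lte(step_mld, 50)
  flat <- mixed_layer_depth(rep(27, 201), depth)
  expect_equal(as.numeric(flat), 200)
  expect_true(attr(flat, "flagged"))
  expect_error(mixed_layer_depth(c(NA, NA, 27), c(5, 8, 20), 0.01),
               "10 m")
})

test_that("mixed-layer depth agrees with a brute-force scan oracle", {
  set.seed(11)
  depth <- 0:300
  for (i in 1:1000) {
    sig <- 27 + cumsum(abs(rnorm(301, 0, 0.002)))
    expect_equal(as.numeric(mixed_layer_depth(sig, depth)),
                 mld_scan_oracle(sig, depth), tolerance = 1e-9)
  }
})

test_that("euphotic depth follows the configured power law", {
  expect_equal(euphotic_depth(1.0), 38.0)
  expect_equal(euphotic_depth(0.5), 38.0 * 0.5^(-0.428))
  chl <- seq(0.1, 5, 0.1)
  expect_true(all(diff(euphotic_depth(chl)) < 0))
  expect_error(euphotic_depth(0), "positive")
})

test_that("polar night follows latitude and solar declination", {
  expect_true(is_polar_night(-69, 172))    # June solstice, Antarctic
  expect_false(is_polar_night(-60, 355))   # December solstice
  # transition within a day of the analytic boundary latitude
  for (doy in c(130, 172, 200)) {
    decl <- phytofate:::solar_declination(doy)
    boundary <- -(90 - abs(decl))
    expect_true(is_polar_night(boundary - 0.2, doy))
    expect_false(is_polar_night(boundary + 0.2, doy))
  }
  # never polar night equatorward of the polar circle
  expect_false(any(vapply(1:365, is_polar_night, NA, latitude = -66.4)))
})

test_that("export depth is the deeper of MLD and Zeu, MLD in polar night", {
  expect_equal(as.numeric(export_depth(100, 60, FALSE)), 100)
  expect_equal(as.numeric(export_depth(30, 70, FALSE)), 70)
  expect_equal(as.numeric(export_depth(150, NULL, TRUE)), 150)
  clipped <- export_depth(100, 200, FALSE, horizon = 175)
  expect_equal(as.numeric(clipped), 175)
  expect_true(attr(clipped, "clipped"))
})

test_that("winter reference selection picks the deepest winter mixing", {
  cfg <- fixed20_config()
  sim <- noiseless_sim()
  series <- prep_series(sim$series, cfg)
  # a mid-bloom cycle in each season resolves to the simulator's own
  # deep-mixing reference
  for (cyc in c(20L, 60L)) {
    ref <- select_winter_reference(series, cyc, cfg)
    expect_identical(as.integer(ref),
                     as.integer(sim$profile_truth$winter_ref_cycle_true[cyc]))
  }
  # series starting after winter has no reference
  summer <- float_series("s", series$profiles[17:25])
  expect_error(select_winter_reference(summer, 20L, cfg),
               class = "phytofate_no_winter_reference")
})

test_that("salinity normalization follows the stated convention", {
  cfg <- fixed20_config()
  d <- 0:500
  ref <- toy_profile(1L, depth = d, sal = rep(34, 501), no3 = rep(30, 501))
  same <- toy_profile(2L, "2015-12-11 12:00:00", depth = d,
                      sal = rep(34, 501), no3 = rep(28, 501))
  expect_equal(salinity_normalize_nitrate(same, ref, cfg),
               rep(28, 501))
  one <- toy_profile(2L, depth = d, sal = rep(33, 501), no3 = rep(30, 501))
  expect_equal(salinity_normalize_nitrate(one, ref, cfg)[1],
               30 * 34 / 33)
  # pure melt dilution is exactly cancelled
  f <- 0.97
  melted <- toy_profile(2L, depth = d, sal = rep(34 * f, 501),
                        no3 = rep(30 * f, 501))
  expect_equal(salinity_normalize_nitrate(melted, ref, cfg),
               rep(30, 501))
})

test_that("advection screen applies the contiguity thresholds", {
  d <- 0:500
  base <- toy_profile(1L, lat = -62, lon = 10, depth = d)
  # the observed maxima from real floats all pass
  ok <- toy_profile(2L, lat = -62.45, lon = 11.1, depth = d,
                    sal = rep(34 + 0.017, 501))
  expect_true(advection_screen(base, ok)$valid)
  # salinity change above 0.05 fails
  bad <- toy_profile(2L, lat = -62, lon = 10, depth = d,
                     sal = rep(34.06, 501))
  scr <- advection_screen(base, bad)
  expect_false(scr$valid)
  expect_match(scr$reason, "salinity")
  # identical profiles pass with zero diagnostics
  self <- advection_screen(base, base)
  expect_true(self$valid)
  expect_identical(c(self$d_salinity_500, self$d_latitude,
                     self$d_longitude), c(0, 0, 0))
  # symmetric in its two profiles, longitude wrapped
  a <- toy_profile(1L, lon = 179.5, depth = d)
  b <- toy_profile(2L, lon = -179.5, depth = d)
  expect_equal(advection_screen(a, b)$d_longitude, 1)
  expect_equal(advection_screen(a, b)[1:4], advection_screen(b, a)[1:4])
})
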