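test_that("a fixed seed gives bit-identical simulations", {
  par <- simulation_params(seed = 9)
  a <- simulate_float(par)
  b <- simulate_float(par)
  expect_identical(lapply(a$series$profiles, unclass),
                   lapply(b$series$profiles, unclass))
  expect_identical(a$truth, b$truth)
})

test_that("infeasible loss fractions are rejected before simulation", {
  expect_error(simulation_params(grazing_fraction = 0.8,
                                 export_fraction = 0.3),
               "losses exceed production")
  expect_error(simulation_params(winter_mld = 80), "90-175")
  expect_error(simulation_params(total_drawdown = 40), "winter_no3")
})

test_that("the truth ledger closes exactly every interval", {
  for (sim in list(noiseless_sim(), noisy_sim())) {
    with(sim$truth, expect_equal(
      production, grazing + mortality + phytodetritus_export + accumulation,
      tolerance = 1e-12))
    expect_true(all(sim$truth$poc_export >= sim$truth$phytodetritus_export))
  }
})

test_that("nitrogen consumed balances the ledger's production", {
  cfg <- fixed20_config(nitrate_smoothing_m = 0)
  # stop before the autumn reset so the final profile still carries the
  # whole seasonal drawdown
  sim <- simulate_float(
    simulation_params(n_cycles = 30, noise_sd = noise_zero,
                      npq_artifact = FALSE, seed = 12),
    cfg)
  series <- prep_series(sim$series, cfg)
  last <- series$profiles[[30]]
  ref <- series$profiles[[sim$profile_truth$winter_ref_cycle_true[30]]]
  dno3 <- ref$nitrate - salinity_normalize_nitrate(last, ref, cfg)
  consumed_c <- 20 * 1.75 *
    phytofate:::trapz_depth(last$depth, dno3, 0, 500)
  ledger_c <- sum(sim$truth$production * 10)
  expect_equal(consumed_c, ledger_c, tolerance = 0.005)
})

test_that("the advection screen passes every noiseless pair", {
  b <- noiseless_budgets()
  expect_true(all(b$screen_valid))
  expect_lt(max(b$d_latitude), 5.5 / 10)
  expect_lt(max(b$d_longitude), 8 / 10)
})

test_that("zero-loss simulations yield no loss estimates", {
  cfg <- fixed20_config(nitrate_smoothing_m = 0)
  sim <- simulate_float(
    simulation_params(grazing_fraction = 0, export_fraction = 0,
                      fecal_export_fraction = 0, mortality_rate_true = 0,
                      noise_sd = noise_zero, npq_artifact = FALSE,
                      seed = 5),
    cfg)
  b <- series_budgets(sim$series, cfg)
  g <- b$grazing_flux
  expect_true(all(is.na(g) | abs(g) < 1e-6))
  expect_true(all(is.na(b$phytodetritus_export_flux) |
                    abs(b$phytodetritus_export_flux) < 1e-6))
})

test_that("an overstated chl:N ratio inflates recovered grazing", {
  sim <- noiseless_sim()
  matched <- annual_average(noiseless_budgets(), "grazing_flux")
  cfg_over <- suppressWarnings(fixed20_config(chl_n_ratio = 2.5))
  over <- annual_average(
    series_budgets(sim$series, cfg_over), "grazing_flux")
  expect_gt(as.numeric(over), as.numeric(matched))
})

test_that("recovery report counts defined estimates and matches truth", {
  rep <- evaluate_recovery(noiseless_sim()$truth, noiseless_budgets())
  expect_setequal(rep$term, c("grazing", "phytodetritus_export",
                              "poc_export", "mortality", "accumulation"))
  expect_true(all(rep$n_defined <= rep$n_intervals))
  poc <- rep[rep$term == "poc_export", ]
  expect_lt(abs(poc$relative_bias), 1e-10)
  expect_error(evaluate_recovery(noiseless_sim()$truth,
                                 transform(noiseless_budgets(),
                                           cycle2 = cycle2 + 500)),
               "mismatched")
})

test_that("the daytime quenching artifact is undone by the correction", {
  cfg <- fixed20_config()
  par_q <- simulation_params(noise_sd = noise_zero, npq_artifact = TRUE,
                             seed = 101)
  sim_q <- simulate_float(par_q, cfg)
  sim_0 <- noiseless_sim()
  i <- 24L  # a mid-bloom daytime profile
  raw_q <- sim_q$series$profiles[[i]]
  raw_0 <- sim_0$series$profiles[[i]]
  expect_lt(raw_q$chlorophyll[1], raw_0$chlorophyll[1])  # depressed
  ctx <- hydro_context(regrid_profile(raw_q, canonical_grid(cfg)), cfg)
  expect_equal(ctx$profile$chlorophyll, raw_0$chlorophyll,
               tolerance = 1e-9)
})
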