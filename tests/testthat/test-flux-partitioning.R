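test_that("potential chlorophyll is linear in drawdown and ratio", {
  expect_equal(chl_star(1.0, 1.75), 1.75)
  expect_equal(chl_star(0, 1.75), 0)
  expect_equal(chl_star(2.0, 2.5), 5.0)
  expect_equal(chl_star(-0.5, 1.75), -0.875)  # negatives pass through
})

test_that("total losses integrate the loss field over the budget column", {
  d <- 0:100
  tl <- total_losses(rep(2, 101), rep(0.5, 101), d, horizon = 175)
  expect_equal(tl$stock, 150)
  expect_equal(tl$field, rep(1.5, 101))
  zero <- total_losses(rep(1, 101), rep(1, 101), d)
  expect_equal(zero$stock, 0)
  # excess chlorophyll at depth: field goes negative, stock counts losses
  # where they occurred
  deep <- total_losses(c(rep(2, 51), rep(0, 50)),
                       c(rep(0.5, 51), rep(0.3, 50)), d)
  expect_equal(deep$field[60], -0.3)
  expect_equal(deep$stock, 75.75)  # clamped field, trapezoid at the edge
})

test_that("phytodetritus stock is the positive excess in the stratum", {
  d <- 100:125
  expect_equal(phytodetritus_stock(rep(0.7, 26), rep(0.2, 26), d,
                                   export_depth = 100, horizon = 125),
               12.5)
  expect_equal(phytodetritus_stock(rep(0.1, 26), rep(0.2, 26), d,
                                   100, 125), 0)
  degenerate <- phytodetritus_stock(rep(1, 26), rep(0, 26), d, 130, 125)
  expect_equal(as.numeric(degenerate), 0)
  expect_false(is.null(attr(degenerate, "flagged")))
  # with no deep drawdown the stock does not depend on the chl:N ratio
  stocks <- vapply(c(1.25, 1.75, 2.5), function(r) {
    phytodetritus_stock(rep(0.7, 26), chl_star(rep(0, 26), r), d, 100, 125)
  }, 0)
  expect_identical(stocks, rep(stocks[1], 3))
})

test_that("phytodetritus export keeps only positive stock changes", {
  expect_equal(phytodetritus_export_flux(10, 20, dt = 10, c_per_chl = 20),
               20)
  same <- phytodetritus_export_flux(10, 10, dt = 10)
  expect_true(is.na(same))
  expect_match(attr(same, "reason"), "non-positive")
  neg <- phytodetritus_export_flux(20, 10, dt = 10)
  expect_true(is.na(neg))
})

test_that("POC export uses the increment below the pair export depth", {
  d <- 0:500
  p1 <- rep(10, 501)
  p2 <- p1 + ifelse(d >= 75 & d <= 175, 5, 0)
  expect_equal(poc_export_flux(p1, p2, d, 75, 175, dt = 10), 50)
  expect_true(is.na(poc_export_flux(p1, p1, d, 75, 175, dt = 10)))
  # increment confined above the export depth is not export
  shallow <- p1 + ifelse(d < 50, 5, 0)
  expect_true(is.na(poc_export_flux(p1, shallow, d, 75, 175, dt = 10)))
  absent <- poc_export_flux(NULL, p2, d, 75, 175, dt = 10)
  expect_match(attr(absent, "reason"), "absent")
})

test_that("mortality is rate times mean stock times carbon ratio", {
  expect_equal(mortality_flux(100, 0.05, 20), 100)
  expect_equal(mortality_flux(100, 0, 20), 0)
  expect_equal(mortality_flux(200, 0.05, 20), 2 * mortality_flux(100, 0.05, 20))
})

test_that("grazing honours the three admissibility criteria", {
  expect_equal(grazing_flux(10, 30, phyto_delta = 0, dt = 10,
                            mortality = 0, c_per_chl = 20), 40)
  c1 <- grazing_flux(30, 28, 0, 10, 0, 20)
  expect_true(is.na(c1))
  expect_match(attr(c1, "reason"), "criterion 1")
  c3 <- grazing_flux(10, 15, phyto_delta = 8, dt = 10, mortality = 0,
                     c_per_chl = 20)
  expect_true(is.na(c3))
  expect_match(attr(c3, "reason"), "criterion 3")
  # criterion 2: a negative phytodetritus change (export below the
  # horizon) must not inflate grazing
  g2 <- grazing_flux(10, 15, phyto_delta = -3, dt = 10, mortality = 0,
                     c_per_chl = 20)
  expect_equal(as.numeric(g2), 2 * 20 / 10)
  # mortality in excess of the increment floors grazing at zero, flagged
  fl <- grazing_flux(10, 15, 0, 10, mortality = 50, c_per_chl = 20)
  expect_identical(as.numeric(fl), 0)
  expect_match(attr(fl, "flagged"), "mortality")
})

test_that("biomass accumulation keeps only positive stock changes", {
  expect_equal(biomass_accumulation_flux(100, 127.15, dt = 10,
                                         c_per_chl = 20), 54.3)
  expect_true(is.na(biomass_accumulation_flux(100, 100, 10)))
  expect_true(is.na(biomass_accumulation_flux(100, 80, 10)))
})

test_that("quenching correction fills the surface from the ML maximum", {
  d <- c(0, 10, 20, 30, 50)
  chl <- c(0.2, 0.2, 1.0, 0.8, 0.5)
  expect_equal(npq_correct(chl, d, mld = 40, is_day = TRUE),
               c(1.0, 1.0, 1.0, 0.8, 0.5))
  expect_identical(npq_correct(chl, d, 40, is_day = FALSE), chl)
  # never decreases a value within the mixed layer
  set.seed(3)
  for (i in 1:50) {
    x <- runif(30)
    dd <- seq(0, 145, 5)
    out <- npq_correct(x, dd, mld = 60, is_day = TRUE)
    expect_true(all(out[dd <= 60] >= x[dd <= 60]))
  }
})

test_that("the loss identity total = local + phytodetritus holds exactly", {
  for (b in list(noiseless_budgets(), noisy_budgets())) {
    ok <- b$screen_valid
    expect_equal(b$total_loss_stock[ok],
                 b$local_loss_t2[ok] + b$phytodetritus_stock_t2[ok],
                 tolerance = 1e-12)
  }
})

test_that("a zero-loss simulation closes: measured chl equals chl*", {
  # smoothing off: closure is tested on the exact fields, not through
  # the noise filter
  cfg <- fixed20_config(nitrate_smoothing_m = 0)
  sim <- simulate_float(
    simulation_params(grazing_fraction = 0, export_fraction = 0,
                      fecal_export_fraction = 0, mortality_rate_true = 0,
                      noise_sd = noise_zero, npq_artifact = FALSE,
                      seed = 5),
    cfg)
  b <- series_budgets(sim$series, cfg)
  expect_lt(max(abs(b$total_loss_stock)), 1e-6)
  # chl equals chl:N times the salinity-normalized drawdown pointwise
  series <- prep_series(sim$series, cfg)
  cyc <- 24L
  ref <- series$profiles[[sim$profile_truth$winter_ref_cycle_true[cyc]]]
  p <- series$profiles[[cyc]]
  dno3 <- ref$nitrate - salinity_normalize_nitrate(p, ref, cfg)
  above <- p$depth <= 30
  expect_equal(p$chlorophyll[above], chl_star(dno3, 1.75)[above],
               tolerance = 1e-6)
})

test_that("a screen-failing pair is skipped with the advection reason", {
  cfg <- fixed20_config()
  series <- prep_series(noiseless_sim()$series, cfg)
  p1 <- series$profiles[[20]]
  p2 <- series$profiles[[21]]
  p2$latitude <- p2$latitude - 6  # jump beyond the 5.5 degree threshold
  ctx1 <- hydro_context(p1, cfg)
  ctx2 <- hydro_context(p2, cfg)
  ref <- series$profiles[[7]]
  row <- pair_budget(ctx1$profile, ctx2$profile, ctx1, ctx2, ref, cfg)
  expect_false(row$screen_valid)
  expect_match(row$reasons, "advection")
  expect_true(is.na(row$grazing_flux))
})

test_that("fluxes are stable under refinement of the depth grid", {
  # smoothing off: the smoother's window is quantized to the grid, the
  # invariance under test is that of the integrals themselves
  cfg1 <- fixed20_config(nitrate_smoothing_m = 0)
  cfg05 <- fixed20_config(grid_step = 0.5, nitrate_smoothing_m = 0)
  par <- simulation_params(noise_sd = noise_zero, npq_artifact = FALSE,
                           seed = 101)
  b1 <- series_budgets(simulate_float(par, cfg1)$series, cfg1)
  b05 <- series_budgets(simulate_float(par, cfg05)$series, cfg05)
  for (term in c("grazing_flux", "phytodetritus_export_flux",
                 "poc_export_flux")) {
    x1 <- b1[[term]]; x2 <- b05[[term]]
    both <- !is.na(x1) & !is.na(x2) & x1 > 5
    expect_gt(sum(both), 5)
    expect_lt(max(abs(x2[both] - x1[both]) / x1[both]), 0.001)
  }
})
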