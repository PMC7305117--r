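# Forward simulation of a sea-ice-zone BGC float: winter nitrate reset by
# deep mixing, a seasonal mixed-layer cycle, an ice-edge bloom consuming
# nitrate at a prescribed chl:N ratio, prescribed grazing / mortality /
# export fates, phytodetritus (and faecal-pellet POC) deposition in the
# export stratum, sea-ice-melt salinity dilution (with proportional
# nitrate dilution), sensor noise and an optional daytime quenching
# artifact. Every prescribed flux is written to a truth ledger so the
# inversion can be verified interval by interval.

#' Parameters of the synthetic float
#'
#' Defaults describe a two-year float at ten-day cadence near 62.5 S:
#' winter mixed layer 125 m (seasonal range 30-125 m), winter nitrate
#' 30 umol l-1, a 120-day summer bloom starting 1 December that draws
#' down 8 umol l-1 in the upper 30 m, of which 60 percent of production
#' is grazed and 10 percent exported as phytodetritus; half of the grazed
#' carbon is re-exported as faecal-pellet POC. The true carbon
#' bookkeeping uses a fixed 20 ug C per ug chl so that recovery tests are
#' independent of the conversion strategy.
#'
#' @param n_cycles Number of profiles (default 73, two years at 10-day
#'   cadence).
#' @param cadence_days Days between profiles.
#' @param start_date First profile date (a winter date, so the first
#'   season has a nitrate reference).
#' @param latitude0,longitude0 Initial position, degrees.
#' @param drift Degrees per cycle `c(dlat, dlon)`; defaults an order of
#'   magnitude below the advection-screen thresholds.
#' @param winter_no3 Deep/winter nitrate, umol l-1.
#' @param winter_mld,summer_mld Seasonal mixed-layer extremes, m
#'   (winter_mld in 90-175 m).
#' @param chl_n_true True chl:N synthesis ratio, ug chl (umol N)-1.
#' @param grazing_fraction,export_fraction Fractions of production grazed
#'   and exported as phytodetritus (sum <= 1).
#' @param fecal_export_fraction Fraction of grazed carbon re-exported to
#'   the export stratum as faecal-pellet POC.
#' @param mortality_rate_true Mortality rate applied to the standing
#'   bloom chlorophyll, d-1.
#' @param bloom_onset_doy,bloom_duration_days Bloom calendar (day of
#'   year; duration in days).
#' @param total_drawdown Seasonal nitrate drawdown in the production
#'   layer, umol l-1.
#' @param production_depth Depth of the production layer, m (taper to
#'   zero at this depth; keep at or above `summer_mld` so drawdown stays
#'   above the export depth).
#' @param melt_salinity_anomaly Summer mixed-layer freshening, psu
#'   (negative).
#' @param background_chl Persistent non-bloom chlorophyll, ug l-1
#'   (default 0: winter chlorophyll is near zero after the bloom decays;
#'   a nonzero background makes the mortality subtraction over-correct
#'   early-season grazing, a genuine limitation of the method discussed
#'   in the vignette).
#' @param poc_background Background POC, ug C l-1.
#' @param poc_live_ratio POC per chlorophyll of living biomass,
#'   ug C (ug chl)-1.
#' @param phyto_decay_efold E-folding (days) of phytodetritus decay after
#'   the bloom (material leaving the 0-175 m column).
#' @param reset_efold E-folding (days) of the autumn/winter nitrate
#'   reset by deep mixing.
#' @param noise_sd Named relative noise levels (multiplicative lognormal,
#'   independent across depth bins) for salinity, nitrate, chlorophyll,
#'   poc, bbp700; the temperature entry is an additive sd in degC.
#' @param npq_artifact Apply a daytime surface quenching depression.
#' @param npq_depth,npq_factor Quenching ramp: chlorophyll above
#'   `npq_depth` m is multiplied by a factor rising from `npq_factor` at
#'   the surface to 1 at `npq_depth`.
#' @param bbp_slope,bbp_intercept Linear POC-to-bbp inverse used to emit
#'   backscatter (matches [poc_from_bbp()]).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(n_cycles = 73,
                              cadence_days = 10,
                              start_date = "2015-07-01",
                              latitude0 = -62.5,
                              longitude0 = 0,
                              drift = c(-0.01, 0.05),
                              winter_no3 = 30,
                              winter_mld = 125,
                              summer_mld = 30,
                              chl_n_true = 1.75,
                              grazing_fraction = 0.6,
                              export_fraction = 0.1,
                              fecal_export_fraction = 0.5,
                              mortality_rate_true = 0.05,
                              bloom_onset_doy = 335,
                              bloom_duration_days = 120,
                              total_drawdown = 8,
                              production_depth = 30,
                              melt_salinity_anomaly = -0.3,
                              background_chl = 0,
                              poc_background = 5,
                              poc_live_ratio = 60,
                              phyto_decay_efold = 30,
                              reset_efold = 20,
                              noise_sd = c(temperature = 0.01,
                                           salinity = 3e-5,
                                           nitrate = 0.01,
                                           chlorophyll = 0.05,
                                           poc = 0.05,
                                           bbp700 = 0.05),
                              npq_artifact = TRUE,
                              npq_depth = 15,
                              npq_factor = 0.5,
                              bbp_slope = 31200,
                              bbp_intercept = 3.0,
                              seed = 42) {
  p <- as.list(environment())
  class(p) <- "simulation_params"
  validate_simulation_params(p)
}

validate_simulation_params <- function(p) {
  stopifnot(p$n_cycles >= 2, p$cadence_days > 0)
  fr <- c(p$grazing_fraction, p$export_fraction, p$fecal_export_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$grazing_fraction + p$export_fraction > 1) {
    stop("infeasible parameters: grazing_fraction + export_fraction > 1 ",
         "(losses exceed production)")
  }
  if (p$winter_mld < 90 || p$winter_mld > 175) {
    stop("winter_mld must lie in the observed 90-175 m range")
  }
  if (p$summer_mld <= 0 || p$summer_mld >= p$winter_mld) {
    stop("summer_mld must be positive and shallower than winter_mld")
  }
  if (p$total_drawdown <= 0 || p$total_drawdown >= p$winter_no3) {
    stop("total_drawdown must be positive and below winter_no3")
  }
  if (p$production_depth > p$summer_mld) {
    stop("production_depth must not exceed summer_mld ",
         "(drawdown must stay above the export depth)")
  }
  if (p$mortality_rate_true < 0) stop("mortality_rate_true must be >= 0")
  need <- c("temperature", "salinity", "nitrate", "chlorophyll", "poc",
            "bbp700")
  if (!all(need %in% names(p$noise_sd))) {
    stop("noise_sd must be named for: ", paste(need, collapse = ", "))
  }
  p
}

# Smooth seasonal weights (southern hemisphere): winter weight peaks at
# day 227 (mid-August), summer weight at day 45 (mid-February). The cube
# sharpens the transitions so the mixed layer collapses quickly at ice
# melt, as observed in the seasonal ice zone.
season_weight <- function(doy, peak_doy, power = 3) {
  ((1 + cos(2 * pi * (doy - peak_doy) / 365.25)) / 2)^power
}

sim_mld <- function(doy, params) {
  params$summer_mld + (params$winter_mld - params$summer_mld) *
    season_weight(doy, 227)
}

# Production-layer vertical shape: uniform to 60 percent of the layer,
# cosine taper to zero at production_depth.
production_shape <- function(z, production_depth) {
  z1 <- 0.6 * production_depth
  w <- ifelse(z <= z1, 1,
              ifelse(z >= production_depth, 0,
                     (1 + cos(pi * (z - z1) / (production_depth - z1))) / 2))
  w
}

# Deposit shape for phytodetritus / faecal POC: uniform between top and
# bottom with 3-m cosine tapers; returns a density (per m) integrating
# to 1.
deposit_shape <- function(z, top, bottom, taper = 3) {
  w <- rep(0, length(z))
  core <- z >= top + taper & z <= bottom - taper
  up <- z >= top & z < top + taper
  dn <- z > bottom - taper & z <= bottom
  w[core] <- 1
  w[up] <- (1 - cos(pi * (z[up] - top) / taper)) / 2
  w[dn] <- (1 - cos(pi * (bottom - z[dn]) / taper)) / 2
  s <- trapz_depth(z, w, min(z), max(z))
  if (s <= 0) stop("degenerate deposit stratum")
  w / s
}

lognormal_factor <- function(n, rel_sd) {
  if (rel_sd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# True export depth under the same conventions as the inversion: the
# deeper of MLD and Zeu (Zeu undefined at zero surface chlorophyll),
# clipped to the export horizon.
sim_export_depth <- function(chl_surface, mld, config) {
  zeu <- if (is.finite(chl_surface) && chl_surface > 0) {
    euphotic_depth(chl_surface, config$zeu_c1, config$zeu_c2)
  } else NA_real_
  ed <- if (is.finite(zeu)) max(mld, zeu) else mld
  min(ed, config$export_horizon)
}

season_of <- function(date) {
  y <- as.integer(format(date, "%Y"))
  ifelse(as.integer(format(date, "%m")) >= 7L, y, y - 1L)
}

#' Simulate a BGC float with a ground-truth flux ledger
#'
#' @param params A [simulation_params()].
#' @param config A [pipeline_config()]; supplies the working grid, the
#'   euphotic-depth coefficients and the winter window so that the
#'   simulated "true" export depths use the same conventions the
#'   inversion will.
#' @return A list of class `float_simulation`: `series` (a
#'   [float_series()]), `truth` (per-interval ledger, mg C m-2 d-1, with
#'   exact closure production = grazing + mortality + export +
#'   accumulation), `profile_truth` (per-profile true MLD, export depth,
#'   surface chlorophyll, ML POC:chl) and `params`.
#' @export
simulate_float <- function(params = simulation_params(),
                           config = pipeline_config()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  z <- canonical_grid(config)
  nz <- length(z)
  nc <- params$n_cycles
  dt <- params$cadence_days
  dates <- as.POSIXct(paste(as.Date(params$start_date) +
                            (seq_len(nc) - 1L) * dt, "12:00:00"),
                      tz = "UTC")
  doys <- as.integer(format(dates, "%j"))
  lats <- params$latitude0 + (seq_len(nc) - 1L) * params$drift[1L]
  lons <- params$longitude0 + (seq_len(nc) - 1L) * params$drift[2L]

  s_deep <- 34.0 + 0.7 * z / 500
  t_deep <- -1.5 + 2.3 * z / 500

  # --- physics first: mixed layer, T/S, per-season winter reference ----
  mld_true <- sim_mld(doys, params)
  t_ml <- -1.8 + 1.6 * season_weight(doys, 45, power = 2)
  melt <- params$melt_salinity_anomaly * season_weight(doys, 45)

  ml_salinity <- vapply(seq_len(nc), function(i) {
    m <- mld_true[i]
    target <- potential_density_anomaly(
      stats::approx(z, t_deep, m)$y, stats::approx(z, s_deep, m)$y,
      m, lats[i]) - config$mld_delta_sigma
    stats::uniroot(function(s) {
      potential_density_anomaly(t_ml[i], s, 0, lats[i]) - target
    }, c(30, 36), tol = 1e-10)$root
  }, 0) + melt

  S <- T <- matrix(0, nz, nc)
  for (i in seq_len(nc)) {
    ml <- z <= mld_true[i]
    S[, i] <- ifelse(ml, ml_salinity[i], s_deep)
    T[, i] <- ifelse(ml, t_ml[i], t_deep)
  }

  seasons <- season_of(dates)
  win_ref_idx <- vapply(unique(seasons), function(sy) {
    w1 <- as.POSIXct(paste0(sy, "-", config$winter_window[1L]), tz = "UTC")
    w2 <- as.POSIXct(paste0(sy, "-", config$winter_window[2L]), tz = "UTC") +
      86400
    cand <- which(dates >= w1 & dates < w2)
    if (!length(cand)) return(NA_integer_)
    best <- cand[mld_true[cand] == max(mld_true[cand])]
    best[length(best)]
  }, 0L)
  names(win_ref_idx) <- as.character(unique(seasons))

  # --- biology: step the ideal fields cycle by cycle ------------------
  w_prod <- production_shape(z, params$production_depth)
  onset_date <- function(sy) {
    as.POSIXct(paste0(sy, "-01-01 12:00:00"), tz = "UTC") +
      (params$bloom_onset_doy - 1) * 86400
  }
  drawdown <- rep(0, nz)     # cumulative nitrate consumed, umol l-1
  bloom_chl <- rep(0, nz)    # standing bloom chlorophyll, ug l-1
  phyto_chl <- rep(0, nz)    # phytodetritus chlorophyll, ug l-1
  fecal_poc <- rep(0, nz)    # faecal-pellet POC, ug C l-1

  r <- params$mortality_rate_true
  c20 <- 20  # true carbon bookkeeping, ug C per ug chl
  dur <- params$bloom_duration_days

  profiles <- vector("list", nc)
  truth <- vector("list", nc)
  profile_truth <- vector("list", nc)
  ed_true_prev <- NA_real_

  for (i in seq_len(nc)) {
    if (i > 1L) {
      sy <- seasons[i]
      t0 <- as.numeric(dates[i - 1L] - onset_date(sy), units = "days")
      t1 <- as.numeric(dates[i] - onset_date(sy), units = "days")
      s0 <- min(max(t0, 0), dur)
      s1 <- min(max(t1, 0), dur)
      uptake_col <- params$total_drawdown / 2 *
        (cos(pi * s0 / dur) - cos(pi * s1 / dur))
      uptake <- uptake_col * w_prod
      drawdown <- drawdown + uptake

      chl_prod <- params$chl_n_true * uptake
      grazed <- params$grazing_fraction * chl_prod
      exported <- params$export_fraction * chl_prod
      add <- chl_prod - grazed - exported
      died <- r * dt * (bloom_chl + add / 2) / (1 + r * dt / 2)
      bloom_chl <- bloom_chl + add - died

      # nitrate reset by deepening mixing, from 30 d after bloom end;
      # once winter mixing reaches 90 m the reset is complete (upper-ocean
      # nitrate uniform and equal to the deep concentration)
      reset_start <- onset_date(sy) + (dur + 30) * 86400
      if (dates[i] > reset_start ||
          (t1 < 0 && dates[i] < onset_date(sy))) {
        drawdown <- drawdown * exp(-dt / params$reset_efold)
        if (mld_true[i] >= 90) drawdown[] <- 0
      }

      # phytodetritus + faecal deposition in the export stratum
      chl_surf_now <- bloom_chl[1L] + params$background_chl
      ed_now <- sim_export_depth(chl_surf_now, mld_true[i], config)
      dep_mass_chl <- trapz_depth(z, exported, 0, max(z))
      fecal_c <- params$fecal_export_fraction * c20 *
        trapz_depth(z, grazed, 0, max(z))
      top <- max(110, ed_true_prev, ed_now, na.rm = TRUE) + 3
      bottom <- config$export_horizon - 3
      if ((dep_mass_chl > 0 || fecal_c > 0) && top < bottom - 6) {
        shape <- deposit_shape(z, top, bottom)
        phyto_chl <- phyto_chl + shape * dep_mass_chl
        fecal_poc <- fecal_poc + shape * fecal_c
      } else if (dep_mass_chl <= 0 && fecal_c <= 0) {
        decay <- exp(-dt / params$phyto_decay_efold)
        phyto_chl <- phyto_chl * decay
        fecal_poc <- fecal_poc * decay
      }

      production_c <- c20 * trapz_depth(z, chl_prod, 0, max(z)) / dt
      grazing_c <- params$grazing_fraction * production_c
      export_c <- params$export_fraction * production_c
      mortality_c <- c20 * trapz_depth(z, died, 0, max(z)) / dt
      truth[[i]] <- data.frame(
        cycle1 = i - 1L, cycle2 = i, time2 = dates[i],
        production = production_c, grazing = grazing_c,
        mortality = mortality_c, phytodetritus_export = export_c,
        poc_export = export_c + fecal_c / dt,
        accumulation = production_c - grazing_c - export_c - mortality_c)
    }

    # --- emit the measured profile ---------------------------------
    chl_surf <- bloom_chl[1L] + params$background_chl
    ed_t <- sim_export_depth(chl_surf, mld_true[i], config)
    ed_true_prev <- ed_t

    s_winter <- S[, win_ref_idx[[as.character(seasons[i])]]]
    no3_ideal <- params$winter_no3 - drawdown
    no3 <- no3_ideal * S[, i] / s_winter
    chl <- bloom_chl + params$background_chl + phyto_chl
    poc <- params$poc_background +
      params$poc_live_ratio * (bloom_chl + params$background_chl) +
      c20 * phyto_chl + fecal_poc

    in_ml <- z <= mld_true[i]
    # NA below the detection floor used by the estimator
    ml_poc_chl <- if (mean(chl[in_ml]) >= 0.01) {
      mean(poc[in_ml]) / mean(chl[in_ml])
    } else NA_real_

    day <- solar_elevation(lats[i], lons[i], dates[i]) > 0
    if (params$npq_artifact && day) {
      ramp <- z < params$npq_depth
      chl[ramp] <- chl[ramp] *
        (params$npq_factor + (1 - params$npq_factor) *
           z[ramp] / params$npq_depth)
    }

    ns <- params$noise_sd
    temp_i <- T[, i] + stats::rnorm(nz, 0, max(ns[["temperature"]], 0))
    sal_i <- S[, i] * lognormal_factor(nz, ns[["salinity"]])
    no3_i <- no3 * lognormal_factor(nz, ns[["nitrate"]])
    chl_i <- chl * lognormal_factor(nz, ns[["chlorophyll"]])
    poc_i <- poc * lognormal_factor(nz, ns[["poc"]])
    # backscatter emitted as the exact linear inverse of the POC channel,
    # so poc_from_bbp() round-trips; bbp carries the POC noise
    bbp_i <- pmax(poc_i - params$bbp_intercept, 0) / params$bbp_slope

    profiles[[i]] <- float_profile(
      float_id = "synthetic-0001", cycle = i, time = dates[i],
      latitude = lats[i], longitude = lons[i],
      depth = z, temperature = temp_i, salinity = sal_i,
      nitrate = no3_i, chlorophyll = chl_i, poc = poc_i, bbp700 = bbp_i,
      under_ice = doys[i] >= 166 && doys[i] <= 288)

    profile_truth[[i]] <- data.frame(
      cycle = i, time = dates[i], mld_true = mld_true[i],
      export_depth_true = ed_t, chl_surface_true = chl_surf,
      ml_poc_chl_true = ml_poc_chl,
      winter_ref_cycle_true = win_ref_idx[[as.character(seasons[i])]])
  }

  structure(list(
    series = float_series("synthetic-0001", profiles),
    truth = do.call(rbind, truth[!vapply(truth, is.null, TRUE)]),
    profile_truth = do.call(rbind, profile_truth),
    params = params
  ), class = "float_simulation")
}

#' @export
print.float_simulation <- function(x, ...) {
  cat(sprintf(paste0("<float_simulation> %d cycles, %d truth intervals; ",
                     "chl:N %.2f, grazed %.0f%%, exported %.0f%%\n"),
              length(x$series), nrow(x$truth), x$params$chl_n_true,
              100 * x$params$grazing_fraction,
              100 * x$params$export_fraction))
  invisible(x)
}

#' Compare inverted budgets against the simulator's truth ledger
#'
#' Matches pair budgets to truth intervals by ending cycle and reports,
#' per flux term, the number of defined estimates, pooled means of the
#' estimates and of the truth over the same intervals, the relative bias
#' of those means, the RMSE, and per-interval relative errors (evaluated
#' where the prescribed flux is at least `floor`, since relative error is
#' meaningless at vanishing truth).
#'
#' @param truth Truth ledger from [simulate_float()].
#' @param budgets Budget table from [series_budgets()].
#' @param floor Minimum true flux (mg C m-2 d-1) for per-interval
#'   relative errors.
#' @return data.frame of class `recovery_report`, one row per term.
#' @export
evaluate_recovery <- function(truth, budgets, floor = 10) {
  terms <- c(grazing = "grazing_flux",
             phytodetritus_export = "phytodetritus_export_flux",
             poc_export = "poc_export_flux",
             mortality = "mortality_flux",
             accumulation = "biomass_accumulation_flux")
  m <- match(budgets$cycle2, truth$cycle2)
  if (all(is.na(m))) stop("mismatched series: no common intervals")
  rows <- lapply(names(terms), function(term) {
    est <- budgets[[terms[[term]]]]
    tru <- truth[[term]][m]
    ok <- !is.na(est) & !is.na(tru)
    cmp <- ok & tru >= floor
    rel <- (est[cmp] - tru[cmp]) / tru[cmp]
    data.frame(
      term = term,
      n_intervals = sum(!is.na(m)),
      n_defined = sum(ok),
      mean_estimate = if (any(ok)) mean(est[ok]) else NA_real_,
      mean_truth = if (any(ok)) mean(tru[ok]) else NA_real_,
      relative_bias = if (any(ok) && mean(tru[ok]) != 0)
        (mean(est[ok]) - mean(tru[ok])) / mean(tru[ok]) else NA_real_,
      rmse = if (any(ok)) sqrt(mean((est[ok] - tru[ok])^2)) else NA_real_,
      n_compared = sum(cmp),
      max_rel_error = if (any(cmp)) max(abs(rel)) else NA_real_,
      median_rel_error = if (any(cmp)) stats::median(abs(rel)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "floor") <- floor
  class(out) <- c("recovery_report", class(out))
  out
}
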