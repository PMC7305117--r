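# Assembly of per-pair budgets: the full chain from salinity-normalized
# drawdown to the partitioned carbon fluxes, for one consecutive-profile
# pair and for a whole series.

#' Budget for one consecutive-profile pair
#'
#' Runs the full partitioning chain for a pair: advection screen,
#' salinity-normalized drawdown against the shared winter reference,
#' potential chlorophyll, loss stocks, phytodetritus stock and export,
#' POC export, mortality, grazing and biomass accumulation. Inadmissible
#' terms are NA with the reason recorded; the identity
#' total = local + phytodetritus holds exactly on stocks.
#'
#' @param p1,p2 Consecutive [float_profile()]s on the canonical grid
#'   (quenching-corrected chlorophyll, i.e. `ctx$profile`).
#' @param ctx1,ctx2 Their [hydro_context()]s.
#' @param winter_ref The shared winter reference [float_profile()].
#' @param config A [pipeline_config()].
#' @param strategy Optional [carbon_strategy()] overriding the one
#'   implied by `config`.
#' @return One-row data.frame (class `pair_budget`) with stocks
#'   (mg chl m-2), fluxes (mg C m-2 d-1), screen diagnostics and reason
#'   codes.
#' @export
pair_budget <- function(p1, p2, ctx1, ctx2, winter_ref,
                        config = pipeline_config(), strategy = NULL) {
  scr <- advection_screen(p1, p2, config$screen_thresholds)
  dt <- as.numeric(p2$time - p1$time, units = "days")
  if (dt <= 0) stop("profiles out of order: dt <= 0")
  horizon <- config$export_horizon
  ed_pair <- max(ctx1$export_depth, ctx2$export_depth)

  row <- data.frame(
    float_id = p1$float_id, cycle1 = p1$cycle, cycle2 = p2$cycle,
    time1 = p1$time, time2 = p2$time,
    month = as.integer(format(p2$time, "%m", tz = "UTC")),
    latitude = p2$latitude, longitude = p2$longitude,
    dt_days = dt, export_depth_pair = ed_pair,
    mld1 = ctx1$mld, mld2 = ctx2$mld,
    screen_valid = scr$valid,
    d_salinity_500 = scr$d_salinity_500,
    d_latitude = scr$d_latitude, d_longitude = scr$d_longitude,
    c_per_chl = NA_real_,
    chl_star_stock = NA_real_, total_loss_stock = NA_real_,
    phytodetritus_stock_t1 = NA_real_, phytodetritus_stock_t2 = NA_real_,
    local_loss_t1 = NA_real_, local_loss_t2 = NA_real_,
    phytodetritus_export_flux = NA_real_, poc_export_flux = NA_real_,
    mortality_flux = NA_real_, grazing_flux = NA_real_,
    biomass_accumulation_flux = NA_real_,
    reasons = "", stringsAsFactors = FALSE
  )
  class(row) <- c("pair_budget", class(row))
  reasons <- character(0)

  if (!scr$valid) {
    row$reasons <- paste0("skipped: ", scr$reason)
    return(row)
  }

  if (is.null(strategy)) strategy <- config_strategy(config)
  chl_ctx <- pair_ml_chl(p1, p2, ctx1, ctx2)
  cc <- c_per_chl(strategy, chl_ctx)
  row$c_per_chl <- cc

  depth <- p1$depth
  budget_one <- function(p) {
    no3n <- salinity_normalize_nitrate(p, winter_ref, config)
    no3n_w <- winter_ref$nitrate
    dno3 <- no3n_w - no3n
    cs <- chl_star(dno3, config$chl_n_ratio)
    tl <- total_losses(cs, p$chlorophyll, depth, horizon)
    ph <- phytodetritus_stock(p$chlorophyll, cs, depth, ed_pair, horizon)
    upper <- trapz_depth(depth, p$chlorophyll, 0, ed_pair)
    list(chl_star_stock = trapz_depth(depth, cs, 0, horizon),
         total = tl$stock, phyto = as.numeric(ph),
         local = tl$stock - as.numeric(ph), chl_upper = upper)
  }
  b1 <- budget_one(p1)
  b2 <- budget_one(p2)

  row$chl_star_stock <- b2$chl_star_stock
  row$total_loss_stock <- b2$total
  row$phytodetritus_stock_t1 <- b1$phyto
  row$phytodetritus_stock_t2 <- b2$phyto
  row$local_loss_t1 <- b1$local
  row$local_loss_t2 <- b2$local

  phyto_delta <- b2$phyto - b1$phyto
  pe <- phytodetritus_export_flux(b1$phyto, b2$phyto, dt, cc)
  reasons <- c(reasons, flux_reason(pe, "phytodetritus_export"))
  row$phytodetritus_export_flux <- flux_value(pe)

  po <- poc_export_flux(p1$poc, p2$poc, depth, ed_pair, horizon, dt)
  reasons <- c(reasons, flux_reason(po, "poc_export"))
  row$poc_export_flux <- flux_value(po)

  mean_stock <- mean(c(b1$chl_upper, b2$chl_upper))
  mo <- mortality_flux(mean_stock, config$mortality_rate, cc)
  row$mortality_flux <- flux_value(mo)

  gr <- if (ed_pair >= horizon) {
    # export stratum has zero width: phytodetritus is unobservable, so
    # the admissibility criteria cannot separate export from grazing
    missing_flux("export stratum degenerate (export depth at horizon)")
  } else {
    grazing_flux(b1$local, b2$local, phyto_delta, dt, flux_value(mo), cc)
  }
  reasons <- c(reasons, flux_reason(gr, "grazing"))
  row$grazing_flux <- flux_value(gr)

  ba <- biomass_accumulation_flux(b1$chl_upper, b2$chl_upper, dt, cc)
  reasons <- c(reasons, flux_reason(ba, "accumulation"))
  row$biomass_accumulation_flux <- flux_value(ba)

  row$reasons <- paste(reasons, collapse = "; ")
  row
}

config_strategy <- function(config, ml_ratio_value = NA_real_) {
  carbon_strategy(config$carbon_strategy, alpha = config$carbon_alpha,
                  beta = config$carbon_beta,
                  ml_ratio_value = ml_ratio_value)
}

# Ambient chlorophyll context for the power-law conversion: mean of the
# two profiles' mixed-layer mean (corrected) chlorophyll, floored to stay
# positive for near-zero winter values.
pair_ml_chl <- function(p1, p2, ctx1, ctx2, floor = 1e-3) {
  one <- function(p, ctx) {
    v <- p$chlorophyll[p$depth <= ctx$mld]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  m <- mean(c(one(p1, ctx1), one(p2, ctx2)), na.rm = TRUE)
  max(m, floor, na.rm = TRUE)
}

#' Pair budgets for a whole series
#'
#' Prepares the series (canonical grid, nitrate smoothing), derives the
#' hydrographic context of every profile, selects the winter reference
#' for each pair, and assembles the budget table. Pairs whose later
#' profile has no available winter reference are skipped and counted.
#'
#' @param series A [float_series()].
#' @param config A [pipeline_config()].
#' @param prep Set to FALSE if `series` is already on the canonical grid
#'   and smoothed.
#' @return data.frame with one row per consecutive pair (see
#'   [pair_budget()]); attributes `n_skipped_no_reference`,
#'   `n_skipped_screen`, `ml_poc_chl` and `contexts`.
#' @export
series_budgets <- function(series, config = pipeline_config(),
                           prep = TRUE) {
  if (prep) series <- prep_series(series, config)
  n <- length(series$profiles)
  if (n < 2L) stop("need at least two profiles to form a pair")
  contexts <- lapply(series$profiles, hydro_context, config = config)

  ml_ratio_value <- NA_real_
  if (config$carbon_strategy == "ml_ratio") {
    ml_ratio_value <- ml_poc_chl_ratio(series, contexts,
                                       config$ml_chl_floor)
  }
  strategy <- config_strategy(config, as.numeric(ml_ratio_value))

  cycles <- vapply(series$profiles, function(p) p$cycle, 0L)
  rows <- vector("list", n - 1L)
  n_no_ref <- 0L
  for (i in seq_len(n - 1L)) {
    p2 <- contexts[[i + 1L]]$profile
    ref_cycle <- tryCatch(
      select_winter_reference(series, p2$cycle, config),
      phytofate_no_winter_reference = function(e) NA_integer_)
    if (is.na(ref_cycle)) { n_no_ref <- n_no_ref + 1L; next }
    contexts[[i]]$winter_ref_cycle <- as.integer(ref_cycle)
    contexts[[i + 1L]]$winter_ref_cycle <- as.integer(ref_cycle)
    winter_ref <- series$profiles[[match(as.integer(ref_cycle), cycles)]]
    rows[[i]] <- pair_budget(contexts[[i]]$profile, p2,
                             contexts[[i]], contexts[[i + 1L]],
                             winter_ref, config, strategy)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    stop("no pair could be budgeted (no winter reference available)")
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped_no_reference") <- n_no_ref
  attr(out, "n_skipped_screen") <- sum(!out$screen_valid)
  attr(out, "ml_poc_chl") <- ml_ratio_value
  attr(out, "contexts") <- contexts
  out
}
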