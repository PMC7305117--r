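# Core flux partitioning: potential chlorophyll from nitrate drawdown,
# total and local loss stocks, phytodetritus stock and export flux, POC
# export, mortality, grazing under the three admissibility criteria, and
# biomass accumulation.
#
# Missing (inadmissible) fluxes are returned as NA with a "reason"
# attribute, never as zero.

missing_flux <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Non-photochemical quenching correction
#'
#' Daytime fluorescence is depressed near the surface. For daytime
#' profiles the maximum chlorophyll within the mixed layer is found and
#' all values above its depth are replaced by that maximum; night
#' profiles are returned unchanged.
#'
#' @param chl Chlorophyll per depth, ug l-1.
#' @param depth Depths, m.
#' @param mld Mixed-layer depth, m.
#' @param is_day Logical.
#' @return Corrected chlorophyll vector.
#' @export
npq_correct <- function(chl, depth, mld, is_day) {
  if (!isTRUE(is_day)) return(chl)
  in_ml <- which(depth <= mld & is.finite(chl))
  if (!length(in_ml)) return(chl)
  imax <- in_ml[which.max(chl[in_ml])]
  out <- chl
  shallower <- depth <= depth[imax]
  out[shallower & is.finite(chl)] <- chl[imax]
  out
}

#' Potential chlorophyll from nitrate drawdown
#'
#' `chl*(z) = ratio * dNO3(z)`: the chlorophyll that should be present in
#' the absence of losses, given the salinity-normalized nitrate drawdown
#' relative to the winter reference. Negative drawdown passes through
#' (handled by the downstream admissibility criteria).
#'
#' @param delta_no3 Drawdown per depth, umol l-1 (winter minus current,
#'   both salinity-normalized).
#' @param ratio chl:N ratio, ug chl (umol N)-1.
#' @return Potential chlorophyll per depth, ug l-1.
#' @export
chl_star <- function(delta_no3, ratio = 1.75) {
  ratio * delta_no3
}

#' Total losses of phytoplankton biomass
#'
#' Per-depth loss field `chl*(z) - chl(z)` (signed; negative values at
#' depth are the phytodetritus signal) and the 0-`horizon` loss stock.
#' The stock integrates the positive part of the field by trapezoid, so
#' that losses are counted where they occurred and the identity
#' total = local + export-stratum phytodetritus holds on stocks.
#'
#' @param chl_star Potential chlorophyll per depth, ug l-1.
#' @param chl Measured (quenching-corrected) chlorophyll, ug l-1.
#' @param depth Depths, m.
#' @param horizon Export horizon, m (default 175).
#' @return List: `field` (signed per-depth losses, ug chl l-1) and
#'   `stock` (positive-part integral over 0-horizon, mg chl m-2).
#' @export
total_losses <- function(chl_star, chl, depth, horizon = 175) {
  field <- chl_star - chl
  stock <- trapz_depth(depth, pmax(field, 0), 0, horizon)
  list(field = field, stock = stock)
}

#' Phytodetritus stock in the export stratum
#'
#' Excess chlorophyll relative to the potential chlorophyll, integrated
#' between the export depth and the horizon:
#' `integral of max(0, chl - chl*)` over \[export_depth, horizon\].
#'
#' @inheritParams total_losses
#' @param export_depth Export depth, m.
#' @return Stock in mg chl m-2 (0 with attribute `flagged` when
#'   `export_depth >= horizon`).
#' @export
phytodetritus_stock <- function(chl, chl_star, depth, export_depth,
                                horizon = 175) {
  if (export_depth >= horizon) {
    out <- 0
    attr(out, "flagged") <- "export depth at or below horizon"
    return(out)
  }
  excess <- pmax(chl - chl_star, 0)
  trapz_depth(depth, excess, export_depth, horizon)
}

#' Phytodetritus export flux
#'
#' Positive change of the export-stratum phytodetritus stock between
#' consecutive profiles, converted to carbon. Non-positive changes are
#' missing (they represent export below the horizon, or none).
#'
#' @param stock_t1,stock_t2 Phytodetritus stocks, mg chl m-2.
#' @param dt Elapsed time, days (> 0).
#' @param c_per_chl Carbon conversion, ug C (ug chl)-1.
#' @return Flux in mg C m-2 d-1, or NA with a `reason` attribute.
#' @export
phytodetritus_export_flux <- function(stock_t1, stock_t2, dt,
                                      c_per_chl = 20) {
  stopifnot(dt > 0)
  if (!is.finite(stock_t1) || !is.finite(stock_t2)) {
    return(missing_flux("phytodetritus stock undefined"))
  }
  delta <- stock_t2 - stock_t1
  if (delta <= 0) {
    return(missing_flux("export below horizon or none (non-positive change)"))
  }
  c_per_chl * delta / dt
}

#' POC export flux
#'
#' Increment of depth-integrated POC between the pair export depth (the
#' deeper of the two profiles' export depths) and the horizon, divided by
#' the elapsed time. Non-positive increments and absent POC are missing.
#'
#' @param poc_t1,poc_t2 POC per depth, ug C l-1 (NULL if absent).
#' @param depth Depths, m.
#' @param export_depth_pair Deeper of the two export depths, m.
#' @param horizon Export horizon, m.
#' @param dt Elapsed time, days.
#' @return Flux in mg C m-2 d-1, or NA with a `reason` attribute.
#' @export
poc_export_flux <- function(poc_t1, poc_t2, depth, export_depth_pair,
                            horizon = 175, dt) {
  stopifnot(dt > 0)
  if (is.null(poc_t1) || is.null(poc_t2)) {
    return(missing_flux("POC absent"))
  }
  s1 <- trapz_depth(depth, poc_t1, export_depth_pair, horizon)
  s2 <- trapz_depth(depth, poc_t2, export_depth_pair, horizon)
  if (!is.finite(s1) || !is.finite(s2)) {
    return(missing_flux("POC invalid in export stratum"))
  }
  delta <- s2 - s1  # 1 ug C l-1 over 1 m = 1 mg C m-2
  if (delta <= 0) return(missing_flux("no POC increment in export stratum"))
  delta / dt
}

#' Mortality flux
#'
#' Intrinsic (non-grazing) mortality: a published oceanic rate applied to
#' the mean upper-ocean chlorophyll stock of the pair, converted to
#' carbon.
#'
#' @param chl_stock_upper Mean chlorophyll stock over 0-export depth for
#'   the pair, mg chl m-2.
#' @param rate Mortality rate, d-1 (>= 0).
#' @param c_per_chl Carbon conversion, ug C (ug chl)-1.
#' @return Flux in mg C m-2 d-1.
#' @export
mortality_flux <- function(chl_stock_upper, rate = 0.05, c_per_chl = 20) {
  stopifnot(rate >= 0)
  rate * chl_stock_upper * c_per_chl
}

#' Grazing flux (grazing-by-difference)
#'
#' Grazing (including viral lysis) is the positive increment of local
#' losses minus mortality, under three admissibility criteria:
#' (1) only positive changes in local losses are considered (negative
#' changes indicate nitrate input); (2) only positive changes in
#' phytodetritus are subtracted (negative changes represent export below
#' the horizon and must not inflate grazing); (3) grazing is only
#' computed when the local-loss increment exceeds the phytodetritus
#' increment. A grazing value driven negative by the mortality
#' subtraction is floored at 0 and flagged.
#'
#' @param local_loss_t1,local_loss_t2 Local-loss stocks (total minus
#'   export-stratum phytodetritus), 0-175 m, mg chl m-2.
#' @param phyto_delta Change in export-stratum phytodetritus stock, mg
#'   chl m-2 (signed).
#' @param dt Elapsed time, days.
#' @param mortality Mortality flux, mg C m-2 d-1.
#' @param c_per_chl Carbon conversion, ug C (ug chl)-1.
#' @return Flux in mg C m-2 d-1, or NA with a `reason` attribute; a
#'   floored value carries attribute `flagged`.
#' @export
grazing_flux <- function(local_loss_t1, local_loss_t2, phyto_delta, dt,
                         mortality = 0, c_per_chl = 20) {
  stopifnot(dt > 0)
  if (!is.finite(local_loss_t1) || !is.finite(local_loss_t2)) {
    return(missing_flux("local losses undefined"))
  }
  # Per-profile local losses subtract the signed phytodetritus stock;
  # criterion (2) restores negative phytodetritus changes so that export
  # below the horizon does not masquerade as grazing.
  d_local <- (local_loss_t2 - local_loss_t1) + min(0, phyto_delta)
  if (d_local <= 0) {
    return(missing_flux("criterion 1: non-positive local-loss change"))
  }
  if (d_local <= max(0, phyto_delta)) {
    return(missing_flux(
      "criterion 3: local-loss change not above phytodetritus change"))
  }
  value <- c_per_chl * d_local / dt - mortality
  if (value < 0) {
    value <- 0
    attr(value, "flagged") <- "mortality exceeded local-loss increment"
  }
  value
}

#' Biomass accumulation flux
#'
#' Positive change of the upper-ocean (0-export depth) chlorophyll stock,
#' converted to carbon; declines are losses, not accumulation, and are
#' missing.
#'
#' @param chl_stock_t1,chl_stock_t2 Chlorophyll stocks over 0-export
#'   depth, mg chl m-2.
#' @param dt Elapsed time, days.
#' @param c_per_chl Carbon conversion, ug C (ug chl)-1.
#' @return Flux in mg C m-2 d-1, or NA with a `reason` attribute.
#' @export
biomass_accumulation_flux <- function(chl_stock_t1, chl_stock_t2, dt,
                                      c_per_chl = 20) {
  stopifnot(dt > 0)
  if (!is.finite(chl_stock_t1) || !is.finite(chl_stock_t2)) {
    return(missing_flux("chlorophyll stock undefined"))
  }
  delta <- chl_stock_t2 - chl_stock_t1
  if (delta <= 0) return(missing_flux("no biomass accumulation"))
  c_per_chl * delta / dt
}

flux_value <- function(x) as.numeric(x)
flux_reason <- function(x, label) {
  r <- attr(x, "reason")
  f <- attr(x, "flagged")
  out <- character(0)
  if (!is.null(r)) out <- paste0(label, ": ", r)
  if (!is.null(f) && !isFALSE(f)) out <- c(out, paste0(label, ": ", f))
  out
}
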