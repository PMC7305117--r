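# Physical scaffolding of the method: mixed-layer depth, euphotic depth,
# polar night, export depth, winter reference selection, salinity
# normalization of nitrate, and the between-profile advection screen.

#' Mixed-layer depth from a density threshold
#'
#' Shallowest depth at which sigma0 exceeds its surface value by `delta`
#' kg m-3. The surface reference is the shallowest valid level at or
#' above 10 m depth (floats rarely sample 0 m); the crossing is localized
#' by linear interpolation between the bracketing levels. If the
#' threshold is never exceeded the deepest valid depth is returned with
#' attribute `flagged = TRUE`.
#'
#' @param sigma0 Potential density anomaly per depth, kg m-3.
#' @param depth Depths, m.
#' @param delta Density offset, kg m-3 (default 0.01).
#' @return MLD in m; attribute `flagged` marks the no-crossing convention
#'   case.
#' @export
mixed_layer_depth <- function(sigma0, depth, delta = 0.01) {
  stopifnot(delta > 0, length(sigma0) == length(depth))
  ok <- is.finite(sigma0) & is.finite(depth)
  surf_candidates <- which(ok & depth <= 10)
  if (!length(surf_candidates)) {
    stop("no valid density levels at or above 10 m depth")
  }
  i0 <- surf_candidates[which.min(depth[surf_candidates])]
  idx <- which(ok & depth >= depth[i0])
  dsig <- sigma0[idx] - sigma0[i0]
  above <- which(dsig >= delta)
  if (!length(above)) {
    out <- max(depth[ok])
    attr(out, "flagged") <- TRUE
    return(out)
  }
  k <- above[1L]
  if (k == 1L) {
    out <- depth[idx[1L]]
  } else {
    z1 <- depth[idx[k - 1L]]; z2 <- depth[idx[k]]
    d1 <- dsig[k - 1L]; d2 <- dsig[k]
    out <- z1 + (delta - d1) * (z2 - z1) / (d2 - d1)
  }
  attr(out, "flagged") <- FALSE
  out
}

#' Euphotic depth from surface chlorophyll
#'
#' Power law `Zeu = c1 * chl^(-c2)`: depth of the 2 percent light level
#' estimated from sea-surface chlorophyll. Default coefficients are a
#' standard published chlorophyll-Zeu power law; both are configurable.
#'
#' @param chl_surface Surface chlorophyll, ug l-1 (> 0).
#' @param c1 Scale, m.
#' @param c2 Exponent (dimensionless, > 0).
#' @return Euphotic depth, m.
#' @export
euphotic_depth <- function(chl_surface, c1 = 38.0, c2 = 0.428) {
  if (any(!is.finite(chl_surface)) || any(chl_surface <= 0)) {
    stop("chl_surface must be positive to estimate the euphotic depth")
  }
  c1 * chl_surface^(-c2)
}

# Solar declination, degrees (standard low-precision approximation).
solar_declination <- function(day_of_year) {
  -23.44 * cos(2 * pi * (day_of_year + 10) / 365.25)
}

#' Polar night test
#'
#' TRUE when the sun stays below the horizon all day, i.e. the solar
#' elevation at local solar noon is negative.
#'
#' @param latitude Latitude, decimal degrees (southern hemisphere
#'   negative; must be in \[-90, 0\]).
#' @param day_of_year Integer day of year (1-366).
#' @return Logical.
#' @export
is_polar_night <- function(latitude, day_of_year) {
  stopifnot(all(latitude >= -90), all(latitude <= 0))
  decl <- solar_declination(day_of_year)
  noon_elevation <- 90 - abs(latitude - decl)
  noon_elevation < 0
}

# Solar elevation (degrees) at an instant; used for the day/night
# decision of the quenching correction.
solar_elevation <- function(latitude, longitude, time) {
  doy <- as.integer(format(time, "%j", tz = "UTC"))
  decl <- solar_declination(doy) * pi / 180
  hours_utc <- as.numeric(time - as.POSIXct(format(time, "%Y-%m-%d",
                                                   tz = "UTC"),
                                            tz = "UTC"), units = "hours")
  solar_hour <- (hours_utc + longitude / 15) %% 24
  hour_angle <- (solar_hour - 12) * 15 * pi / 180
  phi <- latitude * pi / 180
  asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hour_angle)) *
    180 / pi
}

#' Export depth
#'
#' The deeper of the mixed-layer depth and the euphotic depth; during the
#' polar night (no surface irradiance, Zeu undefined) the mixed-layer
#' depth alone. Clipped to the export horizon when it would exceed it
#' (attribute `clipped`).
#'
#' @param mld Mixed-layer depth, m.
#' @param zeu Euphotic depth, m, or NULL/NA during the polar night.
#' @param polar_night Logical.
#' @param horizon Export horizon, m (default 175).
#' @return Export depth, m, with attribute `clipped`.
#' @export
export_depth <- function(mld, zeu = NULL, polar_night = FALSE,
                         horizon = 175) {
  stopifnot(is.finite(mld))
  ed <- if (polar_night || is.null(zeu) || !is.finite(zeu)) mld
        else max(mld, zeu)
  clipped <- ed > horizon
  out <- min(ed, horizon)
  attr(out, "clipped") <- clipped
  out
}

#' Per-profile hydrographic context
#'
#' Derives sigma0, MLD, the day/night state, the quenching-corrected
#' chlorophyll, surface chlorophyll, euphotic depth, polar-night flag and
#' export depth for one profile.
#'
#' @param profile A [float_profile()] on the canonical grid.
#' @param config A [pipeline_config()].
#' @return Object of class `hydro_context` with fields `mld`, `zeu`,
#'   `polar_night`, `export_depth`, `winter_ref_cycle` (filled by the
#'   pipeline), `sigma0`, `is_day`, `chl_surface` and `profile` (the
#'   quenching-corrected profile).
#' @export
hydro_context <- function(profile, config = pipeline_config()) {
  sigma0 <- potential_density_anomaly(profile$temperature,
                                      profile$salinity,
                                      profile$depth, profile$latitude)
  mld <- mixed_layer_depth(sigma0, profile$depth, config$mld_delta_sigma)
  doy <- as.integer(format(profile$time, "%j", tz = "UTC"))
  polar_night <- is_polar_night(profile$latitude, doy)
  is_day <- !polar_night &&
    (format(profile$time, "%H%M%S", tz = "UTC") == "000000" ||
     solar_elevation(profile$latitude, profile$longitude,
                     profile$time) > 0)
  corrected <- profile
  corrected$chlorophyll <- npq_correct(profile$chlorophyll, profile$depth,
                                       as.numeric(mld), is_day)
  surf <- corrected$chlorophyll[corrected$depth <= 10]
  chl_surface <- if (all(is.na(surf))) NA_real_ else mean(surf, na.rm = TRUE)
  zeu <- if (!polar_night && is.finite(chl_surface) && chl_surface > 0) {
    euphotic_depth(chl_surface, config$zeu_c1, config$zeu_c2)
  } else NA_real_
  ed <- export_depth(as.numeric(mld), zeu, polar_night,
                     config$export_horizon)
  structure(list(
    cycle = profile$cycle,
    time = profile$time,
    mld = as.numeric(mld),
    mld_flagged = isTRUE(attr(mld, "flagged")),
    zeu = zeu,
    polar_night = polar_night,
    is_day = is_day,
    chl_surface = chl_surface,
    export_depth = as.numeric(ed),
    export_clipped = isTRUE(attr(ed, "clipped")),
    winter_ref_cycle = NA_integer_,
    sigma0 = sigma0,
    profile = corrected
  ), class = "hydro_context")
}

#' @export
print.hydro_context <- function(x, ...) {
  cat(sprintf(paste0("<hydro_context> cycle %d: MLD %.1f m, Zeu %s, ",
                     "export depth %.1f m%s%s\n"),
              x$cycle, x$mld,
              if (is.finite(x$zeu)) sprintf("%.1f m", x$zeu) else "undefined",
              x$export_depth,
              if (x$polar_night) " [polar night]" else "",
              if (x$export_clipped) " [clipped]" else ""))
  invisible(x)
}

winter_window_bounds <- function(year, winter_window) {
  as.POSIXct(paste0(year, "-", winter_window, " 00:00:00"), tz = "UTC")
}

#' Select the winter nitrate reference profile
#'
#' Finds the most recent austral-winter window (default 1 July to 15
#' October) preceding or containing the target profile's time, and
#' returns the cycle with the deepest mixed layer inside that window
#' (ties broken by the latest profile).
#'
#' @param series A [float_series()] on the canonical grid.
#' @param target_cycle Cycle number whose budget needs a reference.
#' @param config A [pipeline_config()] (winter window, MLD threshold).
#' @return The selected cycle id (integer), with attribute `mld`.
#'   Signals an error of class `phytofate_no_winter_reference` when no
#'   profile falls inside the window.
#' @export
select_winter_reference <- function(series, target_cycle,
                                    config = pipeline_config()) {
  cycles <- vapply(series$profiles, function(p) p$cycle, 0L)
  it <- match(target_cycle, cycles)
  if (is.na(it)) stop("target cycle ", target_cycle, " not in series")
  t_target <- series$profiles[[it]]$time
  year <- as.integer(format(t_target, "%Y", tz = "UTC"))
  win <- winter_window_bounds(year, config$winter_window)
  if (t_target < win[1L]) {
    win <- winter_window_bounds(year - 1L, config$winter_window)
  }
  win[2L] <- win[2L] + 86400  # window end date inclusive
  times <- as.POSIXct(vapply(series$profiles,
                             function(p) as.numeric(p$time), 0),
                      origin = "1970-01-01", tz = "UTC")
  inside <- which(times >= win[1L] & times < win[2L])
  if (!length(inside)) {
    stop(structure(class = c("phytofate_no_winter_reference",
                             "error", "condition"),
                   list(message = paste0("no winter reference profile in ",
                                         format(win[1L], "%Y-%m-%d"), " .. ",
                                         format(win[2L] - 86400, "%Y-%m-%d"),
                                         " for cycle ", target_cycle),
                        call = NULL)))
  }
  mlds <- vapply(inside, function(i) {
    p <- series$profiles[[i]]
    sig <- potential_density_anomaly(p$temperature, p$salinity, p$depth,
                                     p$latitude)
    as.numeric(mixed_layer_depth(sig, p$depth, config$mld_delta_sigma))
  }, 0)
  best <- inside[mlds == max(mlds)]
  sel <- best[length(best)]  # tie -> latest
  out <- cycles[sel]
  attr(out, "mld") <- max(mlds)
  out
}

#' Salinity-normalized nitrate
#'
#' Corrects nitrate for dilution/concentration by sea-ice melt and
#' formation: `NO3n(z) = NO3(z) * S_winter(z) / S(z)` depth-by-depth
#' against the winter reference profile (or against its scalar 0-175 m
#' mean salinity when `config$salinity_normalization == "scalar"`).
#'
#' @param profile A [float_profile()] on the canonical grid.
#' @param winter_ref The winter reference [float_profile()] on the same
#'   grid.
#' @param config A [pipeline_config()].
#' @return Normalized nitrate per depth, umol l-1 (NA where either
#'   salinity is invalid or non-positive).
#' @export
salinity_normalize_nitrate <- function(profile, winter_ref,
                                       config = pipeline_config()) {
  if (length(profile$depth) != length(winter_ref$depth) ||
      any(profile$depth != winter_ref$depth)) {
    stop("profile and winter reference must share the canonical grid")
  }
  s <- profile$salinity
  sw <- winter_ref$salinity
  if (config$salinity_normalization == "scalar") {
    in_horizon <- winter_ref$depth <= config$export_horizon
    sw <- rep(mean(sw[in_horizon], na.rm = TRUE), length(sw))
  }
  out <- profile$nitrate * sw / s
  out[!is.finite(s) | s <= 0 | !is.finite(sw)] <- NA_real_
  out
}

#' Advection screen for a consecutive-profile pair
#'
#' Consecutive profiles are treated as contiguous (advection negligible)
#' only when the salinity at 500 m, the latitude and the longitude each
#' change by less than the configured thresholds (defaults 0.05 psu,
#' 5.5 deg, 8 deg). Salinity at 500 m is the nearest valid level within
#' 480-520 m; the longitude difference is wrapped to \[-180, 180\].
#'
#' @param p1,p2 Consecutive [float_profile()]s.
#' @param thresholds Named numeric (salinity, latitude, longitude).
#' @return Object of class `pair_screen`: fields `valid`,
#'   `d_salinity_500`, `d_latitude`, `d_longitude`, `reason`.
#' @export
advection_screen <- function(p1, p2,
                             thresholds = c(salinity = 0.05,
                                            latitude = 5.5,
                                            longitude = 8.0)) {
  s500 <- function(p) {
    band <- which(p$depth >= 480 & p$depth <= 520 & is.finite(p$salinity))
    if (!length(band)) return(NA_real_)
    p$salinity[band[which.min(abs(p$depth[band] - 500))]]
  }
  s1 <- s500(p1); s2 <- s500(p2)
  d_sal <- abs(s2 - s1)
  d_lat <- abs(p2$latitude - p1$latitude)
  d_lon <- abs(((p2$longitude - p1$longitude + 180) %% 360) - 180)
  reason <- NULL
  if (!is.finite(s1) || !is.finite(s2)) {
    reason <- "no valid salinity within 480-520 m"
    valid <- FALSE
  } else {
    checks <- c(salinity = d_sal <= thresholds[["salinity"]],
                latitude = d_lat <= thresholds[["latitude"]],
                longitude = d_lon <= thresholds[["longitude"]])
    valid <- all(checks)
    if (!valid) {
      reason <- paste0("advection: ",
                       paste(names(checks)[!checks], collapse = "+"),
                       " change exceeds threshold")
    }
  }
  structure(list(valid = valid,
                 d_salinity_500 = d_sal,
                 d_latitude = d_lat,
                 d_longitude = d_lon,
                 reason = reason),
            class = "pair_screen")
}

#' @export
print.pair_screen <- function(x, ...) {
  cat(sprintf("<pair_screen> %s  dS500=%.4f dLat=%.3f dLon=%.3f%s\n",
              if (x$valid) "PASS" else "FAIL",
              x$d_salinity_500, x$d_latitude, x$d_longitude,
              if (is.null(x$reason)) "" else paste0("  (", x$reason, ")")))
  invisible(x)
}
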