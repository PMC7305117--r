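# Serialization of float series.
#
# CSV dialect: one row per (cycle, depth); fixed column names
# (float_id, cycle, time, latitude, longitude, under_ice, depth,
# temperature, salinity, nitrate, chlorophyll, poc, bbp700); ISO-8601
# UTC times. Optional variables that were never measured are omitted as
# columns; a variable that is entirely NA within a profile is marked
# absent on reading.
#
# NetCDF dialect: Argo-like layout with dimensions N_LEVELS x N_PROF
# (N_PROF unlimited), per-variable units attributes and a float_id global
# attribute.

CSV_META_COLS <- c("float_id", "cycle", "time", "latitude", "longitude",
                   "under_ice")

#' Read a float profile series
#'
#' @param path Path to a file written by [write_series()] (or any file in
#'   the documented CSV / Argo-like NetCDF dialect).
#' @param format `"csv"` or `"netcdf"`; guessed from the file extension
#'   when omitted.
#' @return A validated, time-sorted [float_series()].
#' @export
read_series <- function(path, format = c("auto", "csv", "netcdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nc$", path, ignore.case = TRUE)) "netcdf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_series_csv(path),
         netcdf = read_series_netcdf(path))
}

#' Write a float profile series
#'
#' @param series A [float_series()].
#' @param path Output path.
#' @inheritParams read_series
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("auto", "csv", "netcdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nc$", path, ignore.case = TRUE)) "netcdf" else "csv"
  }
  stopifnot(inherits(series, "float_series"))
  switch(format,
         csv = write_series_csv(series, path),
         netcdf = write_series_netcdf(series, path))
  invisible(path)
}

series_present_vars <- function(series) {
  if (!length(series$profiles)) return(REQUIRED_VARIABLES)
  PROFILE_VARIABLES[vapply(PROFILE_VARIABLES, function(v) {
    any(vapply(series$profiles, function(p) !is.null(p[[v]]), TRUE))
  }, TRUE)]
}

write_series_csv <- function(series, path) {
  vars <- series_present_vars(series)
  rows <- lapply(series$profiles, function(p) {
    n <- length(p$depth)
    df <- data.frame(
      float_id = rep(p$float_id, n),
      cycle = rep(p$cycle, n),
      time = rep(format(p$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), n),
      latitude = rep(p$latitude, n),
      longitude = rep(p$longitude, n),
      under_ice = rep(p$under_ice, n),
      depth = p$depth,
      stringsAsFactors = FALSE
    )
    for (v in vars) df[[v]] <- if (is.null(p[[v]])) NA_real_ else p[[v]]
    df
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(float_id = character(), cycle = integer(),
                     time = character(), latitude = numeric(),
                     longitude = numeric(), under_ice = logical(),
                     depth = numeric(), stringsAsFactors = FALSE)
    for (v in vars) df[[v]] <- numeric()
    df
  }
  # full (17 significant digit) precision so the round trip is
  # bit-comparable for finite values
  for (v in names(out)) {
    if (is.numeric(out[[v]]) && !is.integer(out[[v]])) {
      out[[v]] <- ifelse(is.na(out[[v]]), "NA",
                         sprintf("%.17g", out[[v]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_req <- setdiff(REQUIRED_VARIABLES, names(df))
  if (length(missing_req)) {
    stop("parse error: required variable(s) missing from ", path, ": ",
         paste(missing_req, collapse = ", "))
  }
  missing_meta <- setdiff(c(CSV_META_COLS[1:5], "depth"), names(df))
  if (length(missing_meta)) {
    stop("parse error: required column(s) missing from ", path, ": ",
         paste(missing_meta, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(float_series("unknown", list()))
  }
  fid <- as.character(df$float_id[1L])
  profiles <- lapply(split(df, df$cycle), function(d) {
    d <- d[order(d$depth), , drop = FALSE]
    args <- list(
      float_id = d$float_id[1L], cycle = d$cycle[1L],
      time = as.POSIXct(d$time[1L], format = "%Y-%m-%dT%H:%M:%SZ",
                        tz = "UTC"),
      latitude = d$latitude[1L], longitude = d$longitude[1L],
      under_ice = if ("under_ice" %in% names(d)) d$under_ice[1L] else NA,
      depth = d$depth
    )
    for (v in PROFILE_VARIABLES) {
      if (!v %in% names(d)) next
      col <- as.numeric(d[[v]])
      optional <- !(v %in% REQUIRED_VARIABLES)
      args[[v]] <- if (optional && all(is.na(col))) NULL else col
    }
    do.call(float_profile, args)
  })
  float_series(fid, unname(profiles))
}

write_series_netcdf <- function(series, path) {
  vars <- series_present_vars(series)
  nprof <- length(series$profiles)
  nlev <- if (nprof) max(vapply(series$profiles,
                                function(p) length(p$depth), 0L)) else 1L
  fill <- 99999
  dim_lev <- ncdf4::ncdim_def("N_LEVELS", "", seq_len(nlev),
                              create_dimvar = FALSE)
  dim_prof <- ncdf4::ncdim_def("N_PROF", "count",
                               as.double(seq_len(nprof)), unlim = TRUE)
  def1 <- function(name, units, prec = "double") {
    ncdf4::ncvar_def(name, units, dim_prof, fill, prec = prec)
  }
  def2 <- function(name, units) {
    ncdf4::ncvar_def(name, units, list(dim_lev, dim_prof), fill,
                     prec = "double")
  }
  nc_names <- c(temperature = "TEMP", salinity = "PSAL", nitrate = "NITRATE",
                chlorophyll = "CHLA", poc = "POC", bbp700 = "BBP700")
  defs <- list(def1("CYCLE_NUMBER", "", prec = "integer"),
               def1("TIME", "seconds since 1970-01-01 00:00:00 UTC"),
               def1("LATITUDE", "degrees_north"),
               def1("LONGITUDE", "degrees_east"),
               def1("UNDER_ICE", "", prec = "integer"),
               def2("DEPTH", VARIABLE_UNITS[["depth"]]))
  for (v in vars) defs <- c(defs, list(def2(nc_names[[v]],
                                            VARIABLE_UNITS[[v]])))
  nc <- ncdf4::nc_create(path, defs, force_v4 = FALSE)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncatt_put(nc, 0, "float_id",
                   if (nprof) series$profiles[[1L]]$float_id
                   else series$float_id)
  ncdf4::ncatt_put(nc, 0, "conventions", "phytofate Argo-like profile file")
  pad <- function(x, n) c(x, rep(NA_real_, n - length(x)))
  for (i in seq_len(nprof)) {
    p <- series$profiles[[i]]
    put1 <- function(name, val) {
      ncdf4::ncvar_put(nc, name, val, start = i, count = 1)
    }
    put1("CYCLE_NUMBER", p$cycle)
    put1("TIME", as.numeric(p$time))
    put1("LATITUDE", p$latitude)
    put1("LONGITUDE", p$longitude)
    put1("UNDER_ICE", if (is.na(p$under_ice)) -1L else as.integer(p$under_ice))
    ncdf4::ncvar_put(nc, "DEPTH", pad(p$depth, nlev),
                     start = c(1, i), count = c(nlev, 1))
    for (v in vars) {
      val <- if (is.null(p[[v]])) rep(NA_real_, nlev) else pad(p[[v]], nlev)
      ncdf4::ncvar_put(nc, nc_names[[v]], val,
                       start = c(1, i), count = c(nlev, 1))
    }
  }
  invisible(path)
}

read_series_netcdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  nc_names <- c(temperature = "TEMP", salinity = "PSAL", nitrate = "NITRATE",
                chlorophyll = "CHLA", poc = "POC", bbp700 = "BBP700")
  have <- names(nc_names)[nc_names %in% names(nc$var)]
  missing_req <- setdiff(REQUIRED_VARIABLES, have)
  if (length(missing_req)) {
    stop("parse error: required variable(s) missing from ", path, ": ",
         paste(missing_req, collapse = ", "))
  }
  fid <- ncdf4::ncatt_get(nc, 0, "float_id")$value
  nprof <- nc$dim$N_PROF$len
  if (nprof == 0L) return(float_series(fid, list()))
  get1 <- function(name) ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
  cycle <- as.integer(get1("CYCLE_NUMBER"))
  time <- as.numeric(get1("TIME"))
  lat <- as.numeric(get1("LATITUDE"))
  lon <- as.numeric(get1("LONGITUDE"))
  uice <- as.integer(get1("UNDER_ICE"))
  depth <- matrix(get1("DEPTH"), ncol = nprof)
  mats <- lapply(nc_names[have], function(nm) matrix(get1(nm), ncol = nprof))
  profiles <- lapply(seq_len(nprof), function(i) {
    d <- depth[, i]
    keep <- is.finite(d)
    args <- list(float_id = fid, cycle = cycle[i],
                 time = as.POSIXct(time[i], origin = "1970-01-01",
                                   tz = "UTC"),
                 latitude = lat[i], longitude = lon[i],
                 under_ice = if (uice[i] < 0 || is.na(uice[i])) NA
                             else as.logical(uice[i]),
                 depth = d[keep])
    for (v in have) {
      col <- mats[[v]][keep, i]
      optional <- !(v %in% REQUIRED_VARIABLES)
      args[[v]] <- if (optional && all(is.na(col))) NULL else col
    }
    do.call(float_profile, args)
  })
  float_series(fid, profiles)
}

#' Regrid a profile onto a target depth grid
#'
#' Linear interpolation within the sampled range of each variable; no
#' extrapolation (depths outside the sampled range become NA). A variable
#' with fewer than two valid samples becomes all-NA with a warning.
#'
#' @param profile A [float_profile()].
#' @param grid Strictly increasing target depths, m.
#' @return A [float_profile()] on `grid`.
#' @export
regrid_profile <- function(profile, grid) {
  stopifnot(inherits(profile, "float_profile"))
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  args <- list(float_id = profile$float_id, cycle = profile$cycle,
               time = profile$time, latitude = profile$latitude,
               longitude = profile$longitude, under_ice = profile$under_ice,
               depth = as.numeric(grid))
  for (v in PROFILE_VARIABLES) {
    src <- profile[[v]]
    if (is.null(src)) { args[v] <- list(NULL); next }
    ok <- is.finite(profile$depth) & is.finite(src)
    if (sum(ok) < 2L) {
      warning("variable '", v, "' has fewer than 2 valid samples; ",
              "marked invalid after regridding (float ", profile$float_id,
              ", cycle ", profile$cycle, ")")
      args[[v]] <- rep(NA_real_, length(grid))
    } else {
      args[[v]] <- stats::approx(profile$depth[ok], src[ok], xout = grid,
                                 method = "linear", rule = 1)$y
    }
  }
  do.call(float_profile, args)
}

#' Regrid every profile of a series onto the canonical grid
#'
#' @param series A [float_series()].
#' @param config A [pipeline_config()]; defines the canonical grid.
#' @return A [float_series()] on the canonical grid.
#' @export
regrid_series <- function(series, config = pipeline_config()) {
  grid <- canonical_grid(config)
  float_series(series$float_id,
               lapply(series$profiles, regrid_profile, grid = grid))
}

#' Prepare a series for budget computation
#'
#' Regrids onto the canonical grid and applies the configured running-mean
#' smoothing to nitrate (sensor-noise suppression before profiles are
#' differenced).
#'
#' @inheritParams regrid_series
#' @return A [float_series()].
#' @export
prep_series <- function(series, config = pipeline_config()) {
  out <- regrid_series(series, config)
  if (config$nitrate_smoothing_m > 0) {
    out$profiles <- lapply(out$profiles, function(p) {
      p$nitrate <- running_mean(p$nitrate, p$depth,
                                config$nitrate_smoothing_m)
      p
    })
  }
  out
}
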