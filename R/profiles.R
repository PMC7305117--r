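# In-memory data model: one vertical station (float_profile) and a
# time-ordered sequence of stations from one float (float_series).
# Invalid data are encoded as NA, never as sentinel numerics; optional
# variables that were not measured are absent (NULL), never zero.

PROFILE_VARIABLES <- c("temperature", "salinity", "nitrate",
                       "chlorophyll", "poc", "bbp700")
REQUIRED_VARIABLES <- c("temperature", "salinity", "nitrate", "chlorophyll")

VARIABLE_UNITS <- c(temperature = "degC", salinity = "psu",
                    nitrate = "umol l-1", chlorophyll = "ug l-1",
                    poc = "ug C l-1", bbp700 = "m-1", depth = "m")

#' A single float profile
#'
#' One vertical station: depth-gridded temperature, salinity, nitrate and
#' chlorophyll (POC and backscatter optional) plus time and position
#' metadata.
#'
#' @param float_id Float identifier (character).
#' @param cycle Integer cycle number.
#' @param time UTC timestamp (`POSIXct`, or anything `as.POSIXct` accepts).
#' @param latitude,longitude Position in decimal degrees (southern-ocean
#'   latitudes are negative).
#' @param depth Strictly increasing depths, m, positive down.
#' @param temperature,salinity,nitrate,chlorophyll Per-depth values
#'   (degC, practical salinity, umol l-1, ug l-1); NA marks invalid.
#' @param poc,bbp700 Optional per-depth POC (ug C l-1) and particulate
#'   backscattering at 700 nm (m-1); `NULL` if not measured.
#' @param under_ice Optional logical flag.
#' @return Object of class `float_profile`.
#' @export
float_profile <- function(float_id, cycle, time, latitude, longitude,
                          depth, temperature, salinity, nitrate,
                          chlorophyll, poc = NULL, bbp700 = NULL,
                          under_ice = NA) {
  time <- as.POSIXct(time, tz = "UTC")
  p <- structure(list(
    float_id = as.character(float_id),
    cycle = as.integer(cycle),
    time = time,
    latitude = as.numeric(latitude),
    longitude = as.numeric(longitude),
    under_ice = as.logical(under_ice),
    depth = as.numeric(depth),
    temperature = as.numeric(temperature),
    salinity = as.numeric(salinity),
    nitrate = as.numeric(nitrate),
    chlorophyll = as.numeric(chlorophyll),
    poc = if (is.null(poc)) NULL else as.numeric(poc),
    bbp700 = if (is.null(bbp700)) NULL else as.numeric(bbp700)
  ), class = "float_profile")
  validate_profile(p)
}

validate_profile <- function(p) {
  n <- length(p$depth)
  if (n == 0L) stop("profile has no depth levels")
  if (any(!is.finite(p$depth))) stop("depth contains non-finite values")
  if (any(diff(p$depth) <= 0)) {
    stop("validation error: depth must be strictly increasing (float ",
         p$float_id, ", cycle ", p$cycle, ")")
  }
  for (v in PROFILE_VARIABLES) {
    if (is.null(p[[v]])) next
    if (length(p[[v]]) != n) {
      stop("variable '", v, "' has length ", length(p[[v]]),
           " but depth has length ", n)
    }
  }
  for (v in c("nitrate", "chlorophyll")) {
    bad <- !is.na(p[[v]]) & p[[v]] < 0
    if (any(bad)) {
      stop("validation error: negative ", v, " at depth ",
           p$depth[which(bad)[1L]], " m")
    }
  }
  p
}

#' @export
print.float_profile <- function(x, ...) {
  cat(sprintf("<float_profile> float %s cycle %d  %s  (%.3f, %.3f)\n",
              x$float_id, x$cycle, format(x$time, "%Y-%m-%d %H:%M UTC"),
              x$latitude, x$longitude))
  opt <- PROFILE_VARIABLES[!vapply(x[PROFILE_VARIABLES], is.null, TRUE)]
  cat(sprintf("  %d levels, %.0f-%.0f m; variables: %s\n",
              length(x$depth), min(x$depth), max(x$depth),
              paste(opt, collapse = ", ")))
  invisible(x)
}

#' A time-ordered series of profiles from one float
#'
#' @param float_id Float identifier.
#' @param profiles List of [float_profile()] objects; they are sorted by
#'   time, which must then be strictly increasing.
#' @return Object of class `float_series`.
#' @export
float_series <- function(float_id, profiles) {
  stopifnot(is.list(profiles))
  if (length(profiles)) {
    times <- vapply(profiles, function(p) as.numeric(p$time), 0)
    profiles <- profiles[order(times)]
    if (any(diff(sort(times)) <= 0)) {
      stop("validation error: profile timestamps must be strictly increasing")
    }
  }
  structure(list(float_id = as.character(float_id), profiles = profiles),
            class = "float_series")
}

#' @export
length.float_series <- function(x) length(x$profiles)

#' @export
print.float_series <- function(x, ...) {
  cat(sprintf("<float_series> float %s: %d profiles\n",
              x$float_id, length(x$profiles)))
  if (length(x$profiles)) {
    t1 <- x$profiles[[1L]]$time
    t2 <- x$profiles[[length(x$profiles)]]$time
    dts <- profile_spacing_days(x)
    cat(sprintf("  %s to %s; median spacing %.1f d\n",
                format(t1, "%Y-%m-%d"), format(t2, "%Y-%m-%d"),
                stats::median(dts)))
  }
  invisible(x)
}

#' Spacing between consecutive profiles, in days
#' @param series A [float_series()].
#' @return Numeric vector of length `length(series) - 1`.
#' @export
profile_spacing_days <- function(series) {
  times <- vapply(series$profiles, function(p) as.numeric(p$time), 0)
  diff(times) / 86400
}

# Trapezoidal depth integral of `values` over [z1, z2], interpolating the
# integrand linearly at the interval endpoints and skipping NA levels.
# 1 ug l-1 integrated over 1 m equals 1 mg m-2.
trapz_depth <- function(depth, values, z1 = min(depth), z2 = max(depth)) {
  ok <- is.finite(depth) & is.finite(values)
  if (sum(ok) < 2L) return(NA_real_)
  d <- depth[ok]; v <- values[ok]
  z1 <- max(z1, min(d)); z2 <- min(z2, max(d))
  if (z2 <= z1) return(0)
  v1 <- stats::approx(d, v, xout = z1, rule = 2)$y
  v2 <- stats::approx(d, v, xout = z2, rule = 2)$y
  inside <- d > z1 & d < z2
  dd <- c(z1, d[inside], z2)
  vv <- c(v1, v[inside], v2)
  sum(diff(dd) * (head2(vv) + vv[-1L]) / 2)
}

head2 <- function(x) x[-length(x)]

# Centred running mean of width `width_m` (in grid units of `depth`),
# ignoring NAs; used to suppress per-level sensor noise before profiles
# are differenced.
running_mean <- function(values, depth, width_m) {
  if (width_m <= 0 || all(is.na(values))) return(values)
  step <- stats::median(diff(depth))
  half <- max(0L, floor((width_m / step - 1) / 2))
  if (half == 0L) return(values)
  n <- length(values)
  out <- values
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- values[j]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out[is.na(values)] <- NA_real_
  out
}
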