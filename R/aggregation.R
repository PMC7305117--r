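# Pooling of pair budgets into summary products: box-plot statistics,
# monthly and latitudinal climatologies, annual averages, percent
# contributions and the chl:N sensitivity table.

#' Box-plot statistics
#'
#' Median, quartiles (linear interpolation between order statistics,
#' quantile type 7), the functional limits
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\], the sample size and the outliers
#' beyond the limits.
#'
#' @param x Numeric vector; NAs dropped.
#' @return List of class `boxplot_stats`: `median`, `q1`, `q3`,
#'   `lower_limit`, `upper_limit`, `n`, `outliers`.
#' @export
boxplot_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(structure(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          lower_limit = NA_real_, upper_limit = NA_real_,
                          n = 0L, outliers = numeric(0)),
                     class = "boxplot_stats"))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L],
                 lower_limit = lo, upper_limit = hi, n = length(x),
                 outliers = x[x < lo | x > hi]),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(paste0("<boxplot_stats> n=%d median=%.3g [Q1=%.3g, Q3=%.3g] ",
                     "limits [%.3g, %.3g], %d outlier(s)\n"),
              x$n, x$median, x$q1, x$q3, x$lower_limit, x$upper_limit,
              length(x$outliers)))
  invisible(x)
}

boxplot_stats_row <- function(x, ...) {
  b <- boxplot_stats(x)
  data.frame(..., median = b$median, q1 = b$q1, q3 = b$q3,
             lower_limit = b$lower_limit, upper_limit = b$upper_limit,
             n = b$n, n_outliers = length(b$outliers),
             stringsAsFactors = FALSE)
}

FLUX_TERMS <- c("phytodetritus_export_flux", "poc_export_flux",
                "grazing_flux", "mortality_flux",
                "biomass_accumulation_flux")

check_term <- function(budgets, term) {
  if (!term %in% names(budgets)) {
    stop("unknown flux term '", term, "'; available: ",
         paste(FLUX_TERMS, collapse = ", "))
  }
}

#' Percent of losses attributable to grazing
#'
#' `100 * grazing / (grazing + phytodetritus)`; the complementary
#' percentage is the phytodetritus contribution, so the two add to 100
#' exactly. Returned unrounded (round for table display).
#'
#' @param grazing_mean Pooled grazing, mg C m-2 d-1 (>= 0).
#' @param phytodetritus_mean Pooled phytodetritus export, mg C m-2 d-1
#'   (>= 0).
#' @return Percent, unrounded. Both inputs zero is undefined (error).
#' @export
percent_grazed <- function(grazing_mean, phytodetritus_mean) {
  if (any(c(grazing_mean, phytodetritus_mean) < 0)) {
    stop("percent_grazed needs non-negative pooled fluxes")
  }
  total <- grazing_mean + phytodetritus_mean
  if (total == 0) stop("percent grazed undefined: both terms are zero")
  100 * grazing_mean / total
}

#' Annual average of a flux term
#'
#' Pooled mean over all defined pair estimates across all seasons
#' (missing estimates excluded); `mode = "monthly"` averages the monthly
#' means instead.
#'
#' @param budgets Budget table from [series_budgets()].
#' @param term Column name, e.g. `"grazing_flux"`.
#' @param mode `"pooled"` or `"monthly"`.
#' @return Mean flux, mg C m-2 d-1, with attribute `n` (defined
#'   estimates).
#' @export
annual_average <- function(budgets, term, mode = c("pooled", "monthly")) {
  mode <- match.arg(mode)
  check_term(budgets, term)
  x <- budgets[[term]]
  ok <- !is.na(x)
  if (!any(ok)) stop("no defined estimate for ", term)
  out <- if (mode == "pooled") {
    mean(x[ok])
  } else {
    mean(tapply(x[ok], budgets$month[ok], mean))
  }
  attr(out, "n") <- sum(ok)
  out
}

#' Monthly climatology of a flux term
#'
#' Box-plot statistics per calendar month; the month of a pair is that of
#' its later profile (the time by which the flux has been realized).
#' Months without estimates are omitted.
#'
#' @inheritParams annual_average
#' @return data.frame, one row per month with estimates.
#' @export
monthly_climatology <- function(budgets, term) {
  check_term(budgets, term)
  x <- budgets[[term]]
  ok <- !is.na(x)
  months <- sort(unique(budgets$month[ok]))
  do.call(rbind, lapply(months, function(mo) {
    boxplot_stats_row(x[ok & budgets$month == mo], month = mo, term = term)
  }))
}

#' Latitudinal climatology of a flux term
#'
#' Box-plot statistics in half-open latitude bins
#' `[lower, lower + bin_width)`; the latitude of a pair is that of its
#' later profile.
#'
#' @inheritParams annual_average
#' @param bin_width Bin width, degrees (default 1).
#' @return data.frame, one row per occupied bin, with `lat_lower`.
#' @export
latitudinal_bins <- function(budgets, term, bin_width = 1) {
  check_term(budgets, term)
  stopifnot(bin_width > 0)
  x <- budgets[[term]]
  ok <- !is.na(x)
  lower <- floor(budgets$latitude / bin_width) * bin_width
  bins <- sort(unique(lower[ok]))
  do.call(rbind, lapply(bins, function(b) {
    boxplot_stats_row(x[ok & lower == b], lat_lower = b, term = term)
  }))
}

#' Sensitivity of the inversion to the chl:N ratio
#'
#' Re-runs the full pipeline for each ratio (default 1.25, 1.75,
#' 2.5 ug chl per umol N) and tabulates, per float and pooled, the mean
#' and standard deviation of phytodetritus export and grazing and the
#' percent grazed.
#'
#' @param series A [float_series()].
#' @param config A [pipeline_config()].
#' @param ratios chl:N ratios to test.
#' @param percent_mode `"mean"`: percent from the pooled means;
#'   `"per_event"`: mean of per-pair percentages (pairs where both terms
#'   are defined).
#' @return data.frame of class `sensitivity_table`.
#' @export
run_sensitivity <- function(series, config = pipeline_config(),
                            ratios = config$sensitivity_ratios,
                            percent_mode = config$percent_mode) {
  stopifnot(all(ratios > 0))
  series <- prep_series(series, config)
  rows <- lapply(ratios, function(r) {
    cfg <- config
    cfg$chl_n_ratio <- r
    b <- suppressWarnings(series_budgets(series, cfg, prep = FALSE))
    sensitivity_rows(b, r, percent_mode)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", class(out))
  out
}

sensitivity_rows <- function(budgets, ratio, percent_mode) {
  one <- function(b, fid) {
    g <- b$grazing_flux[!is.na(b$grazing_flux)]
    p <- b$phytodetritus_export_flux[!is.na(b$phytodetritus_export_flux)]
    pg <- if (percent_mode == "mean") {
      if (length(g) && length(p)) percent_grazed(mean(g), mean(p))
      else NA_real_
    } else {
      both <- !is.na(b$grazing_flux) & !is.na(b$phytodetritus_export_flux)
      if (any(both)) {
        mean(100 * b$grazing_flux[both] /
               (b$grazing_flux[both] + b$phytodetritus_export_flux[both]))
      } else NA_real_
    }
    data.frame(float_id = fid, chl_n_ratio = ratio,
               phytodetritus_mean = if (length(p)) mean(p) else NA_real_,
               phytodetritus_sd = if (length(p) > 1) stats::sd(p)
                                  else NA_real_,
               n_phytodetritus = length(p),
               grazing_mean = if (length(g)) mean(g) else NA_real_,
               grazing_sd = if (length(g) > 1) stats::sd(g) else NA_real_,
               n_grazing = length(g),
               percent_grazed = pg,
               stringsAsFactors = FALSE)
  }
  per_float <- lapply(split(budgets, budgets$float_id),
                      function(b) one(b, b$float_id[1L]))
  rbind(do.call(rbind, per_float), one(budgets, "pooled"))
}
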