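#' Pipeline configuration
#'
#' Collects every tunable constant of the fate-partitioning method in one
#' validated object. All depths are metres (positive down), all fluxes
#' mg C m-2 d-1.
#'
#' @param chl_n_ratio Chlorophyll synthesized per nitrate consumed,
#'   ug chl (umol N)-1. Reference value 1.75; field range 0.34-2.47 (a
#'   warning is issued outside it).
#' @param sensitivity_ratios chl:N ratios used by [run_sensitivity()].
#' @param mld_delta_sigma Potential-density offset from the surface that
#'   defines the mixed-layer depth, kg m-3.
#' @param export_horizon Deepest winter mixed layer, m; losses and export
#'   are evaluated between the surface (or export depth) and this horizon.
#' @param screen_thresholds Named numeric: maximum allowed change between
#'   consecutive profiles in salinity at 500 m (psu), latitude (deg) and
#'   longitude (deg) for the pair to be considered contiguous.
#' @param mortality_rate Phytoplankton mortality rate, d-1, applied to the
#'   mean upper-ocean chlorophyll stock of a profile pair.
#' @param carbon_strategy One of `"fixed20"`, `"power_law"`, `"ml_ratio"`,
#'   see [carbon_strategy()].
#' @param carbon_alpha,carbon_beta Power-law carbon conversion
#'   coefficients (placeholder defaults; see vignette).
#' @param c_per_chl_fixed Fixed conversion, ug C (ug chl)-1 (lower bound 20).
#' @param zeu_c1,zeu_c2 Euphotic-depth power law `Zeu = c1 * chl^(-c2)`.
#' @param winter_window Two `"MM-DD"` strings delimiting the austral
#'   winter window used to pick the nitrate reference profile.
#' @param grid_max,grid_step Canonical working depth grid, m.
#' @param nitrate_smoothing_m Width (m) of the running-mean smoothing
#'   applied to nitrate profiles before differencing; 0 disables.
#' @param ml_chl_floor Minimum mixed-layer mean chlorophyll (ug l-1) for a
#'   profile to enter the ML POC:chl ratio.
#' @param salinity_normalization `"profile"` (depth-by-depth against the
#'   winter salinity profile) or `"scalar"` (against its 0-175 m mean).
#' @param annual_mode `"pooled"` (mean over all pair estimates) or
#'   `"monthly"` (mean of monthly means).
#' @param percent_mode `"mean"` (ratio of pooled means) or `"per_event"`
#'   (mean of per-pair ratios) for percent-grazed summaries.
#' @param bbp_slope,bbp_intercept Linear backscatter-to-POC conversion,
#'   `POC = slope * bbp700 + intercept` (ug C l-1); used only when POC is
#'   absent from the input.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(chl_n_ratio = 1.75,
                            sensitivity_ratios = c(1.25, 1.75, 2.5),
                            mld_delta_sigma = 0.01,
                            export_horizon = 175,
                            screen_thresholds = c(salinity = 0.05,
                                                  latitude = 5.5,
                                                  longitude = 8.0),
                            mortality_rate = 0.05,
                            carbon_strategy = "power_law",
                            carbon_alpha = 90,
                            carbon_beta = 0.6,
                            c_per_chl_fixed = 20,
                            zeu_c1 = 38.0,
                            zeu_c2 = 0.428,
                            winter_window = c("07-01", "10-15"),
                            grid_max = 500,
                            grid_step = 1,
                            nitrate_smoothing_m = 5,
                            ml_chl_floor = 0.01,
                            salinity_normalization = c("profile", "scalar"),
                            annual_mode = c("pooled", "monthly"),
                            percent_mode = c("mean", "per_event"),
                            bbp_slope = 31200,
                            bbp_intercept = 3.0) {
  cfg <- list(
    chl_n_ratio = chl_n_ratio,
    sensitivity_ratios = sort(as.numeric(sensitivity_ratios)),
    mld_delta_sigma = mld_delta_sigma,
    export_horizon = export_horizon,
    screen_thresholds = screen_thresholds,
    mortality_rate = mortality_rate,
    carbon_strategy = match.arg(carbon_strategy,
                                c("fixed20", "power_law", "ml_ratio")),
    carbon_alpha = carbon_alpha,
    carbon_beta = carbon_beta,
    c_per_chl_fixed = c_per_chl_fixed,
    zeu_c1 = zeu_c1,
    zeu_c2 = zeu_c2,
    winter_window = winter_window,
    grid_max = grid_max,
    grid_step = grid_step,
    nitrate_smoothing_m = nitrate_smoothing_m,
    ml_chl_floor = ml_chl_floor,
    salinity_normalization = match.arg(salinity_normalization),
    annual_mode = match.arg(annual_mode),
    percent_mode = match.arg(percent_mode),
    bbp_slope = bbp_slope,
    bbp_intercept = bbp_intercept
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.numeric(cfg$chl_n_ratio), length(cfg$chl_n_ratio) == 1L,
            cfg$chl_n_ratio > 0)
  if (cfg$chl_n_ratio < 0.34 || cfg$chl_n_ratio > 2.47) {
    warning("chl:N ratio ", cfg$chl_n_ratio,
            " is outside the reported field range [0.34, 2.47]")
  }
  if (!is.numeric(cfg$export_horizon) || cfg$export_horizon <= 0) {
    stop("export_horizon must be a positive depth in metres")
  }
  if (cfg$mld_delta_sigma <= 0) stop("mld_delta_sigma must be > 0")
  if (cfg$mortality_rate < 0) stop("mortality_rate must be >= 0")
  thr <- cfg$screen_thresholds
  if (length(thr) != 3L || any(thr <= 0)) {
    stop("screen_thresholds must be three positive numbers ",
         "(salinity, latitude, longitude)")
  }
  if (is.null(names(thr)) || !all(c("salinity", "latitude", "longitude")
                                  %in% names(thr))) {
    names(cfg$screen_thresholds) <- c("salinity", "latitude", "longitude")
  }
  if (cfg$grid_step <= 0 || cfg$grid_max <= cfg$grid_step) {
    stop("grid_step must be > 0 and grid_max > grid_step")
  }
  if (cfg$grid_max < 500) {
    stop("grid_max must reach 500 m (needed by the advection screen)")
  }
  if (cfg$export_horizon >= cfg$grid_max) {
    stop("export_horizon must lie within the working grid")
  }
  if (cfg$zeu_c1 <= 0 || cfg$zeu_c2 <= 0) stop("zeu coefficients must be > 0")
  if (length(cfg$winter_window) != 2L) {
    stop("winter_window must be two 'MM-DD' strings")
  }
  cfg
}

#' Canonical working depth grid
#' @param config A [pipeline_config()].
#' @return Numeric vector of depths, m, positive down.
#' @export
canonical_grid <- function(config = pipeline_config()) {
  seq(0, config$grid_max, by = config$grid_step)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$screen_thresholds)) {
    raw$screen_thresholds <- unlist(raw$screen_thresholds)
  }
  if (!is.null(raw$winter_window)) {
    raw$winter_window <- as.character(unlist(raw$winter_window))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$screen_thresholds <- as.list(out$screen_thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  chl:N ratio      :", x$chl_n_ratio, "ug chl / umol N\n")
  cat("  export horizon   :", x$export_horizon, "m\n")
  cat("  MLD delta-sigma  :", x$mld_delta_sigma, "kg m-3\n")
  cat("  mortality rate   :", x$mortality_rate, "d-1\n")
  cat("  carbon strategy  :", x$carbon_strategy, "\n")
  cat("  screen thresholds:",
      paste(sprintf("%s=%g", names(x$screen_thresholds),
                    x$screen_thresholds), collapse = ", "), "\n")
  invisible(x)
}
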