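# Shared fixtures. Simulations are deterministic (fixed seeds) and cached
# so the suite builds each study condition once.

noise_zero <- c(temperature = 0, salinity = 0, nitrate = 0,
                chlorophyll = 0, poc = 0, bbp700 = 0)

fixed20_config <- function(...) {
  pipeline_config(carbon_strategy = "fixed20", ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Matched, noiseless study conditions (quenching artifact off).
noiseless_sim <- function() {
  cached("sim0", simulate_float(
    simulation_params(noise_sd = noise_zero, npq_artifact = FALSE,
                      seed = 101),
    fixed20_config()))
}

noiseless_budgets <- function() {
  cached("bud0", series_budgets(noiseless_sim()$series, fixed20_config()))
}

# Same conditions with 5% optical-sensor noise (instrument-level nitrate
# and CTD noise) and the daytime quenching artifact on.
noisy_sim <- function() {
  cached("simN", simulate_float(simulation_params(seed = 1),
                                fixed20_config()))
}

noisy_budgets <- function() {
  cached("budN", series_budgets(noisy_sim()$series, fixed20_config()))
}

# A small hand-made profile for unit tests.
toy_profile <- function(cycle = 1L, time = "2015-12-01 12:00:00",
                        lat = -62, lon = 0, depth = 0:200,
                        chl = NULL, no3 = NULL, sal = NULL, tem = NULL,
                        poc = NULL) {
  n <- length(depth)
  float_profile("toy", cycle, as.POSIXct(time, tz = "UTC"), lat, lon,
                depth = depth,
                temperature = if (is.null(tem)) rep(-1, n) else tem,
                salinity = if (is.null(sal)) rep(34, n) else sal,
                nitrate = if (is.null(no3)) rep(30, n) else no3,
                chlorophyll = if (is.null(chl)) rep(0.5, n) else chl,
                poc = poc)
}

# Independent brute-force MLD oracle: linear scan with interpolation of
# the threshold crossing, written as an explicit loop.
mld_scan_oracle <- function(sigma0, depth, delta = 0.01) {
  ref <- sigma0[1L]
  for (k in seq_along(depth)[-1L]) {
    if (sigma0[k] - ref >= delta) {
      d1 <- sigma0[k - 1L] - ref
      d2 <- sigma0[k] - ref
      return(depth[k - 1L] +
               (delta - d1) * (depth[k] - depth[k - 1L]) / (d2 - d1))
    }
  }
  depth[length(depth)]
}

# Independent type-7 quantile oracle from sorted order statistics.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
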