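# Chlorophyll-to-carbon conversion under the three strategies:
# a fixed lower-bound ratio of 20 ug C per ug chl, a power law in ambient
# chlorophyll, and the mixed-layer POC:chl ratio measured per float.

#' Define a chlorophyll-to-carbon conversion strategy
#'
#' @param kind `"fixed20"` (exactly 20 ug C per ug chl, the lower bound
#'   under saturating light and high nutrients), `"power_law"`
#'   (`ratio = alpha * chl^(beta - 1)`, varying with ambient
#'   chlorophyll), or `"ml_ratio"` (the float's mean mixed-layer POC:chl
#'   ratio, see [ml_poc_chl_ratio()]).
#' @param alpha Power-law scale, ug C (ug chl)-1 at 1 ug chl l-1.
#' @param beta Power-law exponent (dimensionless).
#' @param ml_ratio_value Ratio for `kind = "ml_ratio"`, ug C (ug chl)-1.
#' @return Object of class `carbon_strategy`.
#' @export
carbon_strategy <- function(kind = c("fixed20", "power_law", "ml_ratio"),
                            alpha = 90, beta = 0.6,
                            ml_ratio_value = NA_real_) {
  kind <- match.arg(kind)
  if (alpha <= 0) stop("alpha must be > 0")
  if (kind == "ml_ratio" && is.finite(ml_ratio_value) &&
      ml_ratio_value <= 0) {
    stop("ml_ratio_value must be > 0")
  }
  structure(list(kind = kind, alpha = alpha, beta = beta,
                 ml_ratio_value = ml_ratio_value),
            class = "carbon_strategy")
}

#' Convert a chlorophyll amount to carbon
#'
#' Linear in the chlorophyll amount at fixed context; the ratio applied
#' is exactly 20 for `fixed20`, `alpha * chl_context^(beta - 1)` for
#' `power_law`, and the per-float mixed-layer POC:chl ratio for
#' `ml_ratio`.
#'
#' @param chl_amount Amount of chlorophyll (ug chl, or mg chl m-2 for
#'   stocks; units carry through).
#' @param strategy A [carbon_strategy()].
#' @param chl_context Ambient chlorophyll, ug l-1 (required for
#'   `power_law`).
#' @return Carbon amount (ug C or mg C m-2).
#' @export
carbon_from_chl <- function(chl_amount, strategy, chl_context = NULL) {
  stopifnot(inherits(strategy, "carbon_strategy"))
  c_per_chl(strategy, chl_context) * chl_amount
}

# Scalar conversion ratio, ug C per ug chl.
c_per_chl <- function(strategy, chl_context = NULL) {
  switch(strategy$kind,
    fixed20 = 20,
    power_law = {
      if (is.null(chl_context) || !is.finite(chl_context) ||
          chl_context <= 0) {
        stop("power_law conversion needs a positive ambient chlorophyll")
      }
      strategy$alpha * chl_context^(strategy$beta - 1)
    },
    ml_ratio = {
      if (!is.finite(strategy$ml_ratio_value)) {
        stop("ml_ratio strategy used before the float's ML POC:chl ratio ",
             "was computed (see ml_poc_chl_ratio)")
      }
      strategy$ml_ratio_value
    })
}

#' Mean mixed-layer POC:chl ratio of a float
#'
#' For each profile with valid POC and chlorophyll inside the mixed
#' layer, computes (ML-mean POC) / (ML-mean chl); profiles whose ML-mean
#' chlorophyll falls below `chl_floor` are excluded (and counted in the
#' `n_excluded` attribute). The float ratio is the mean over eligible
#' profiles. Chlorophyll is the quenching-corrected profile carried by
#' the contexts.
#'
#' @param series A [float_series()] on the canonical grid.
#' @param contexts List of [hydro_context()]s matching `series`.
#' @param chl_floor Minimum ML-mean chlorophyll, ug l-1.
#' @return Ratio in ug C (ug chl)-1 with attributes `n` and `n_excluded`.
#' @export
ml_poc_chl_ratio <- function(series, contexts, chl_floor = 0.01) {
  stopifnot(length(series$profiles) == length(contexts))
  ratios <- rep(NA_real_, length(contexts))
  excluded <- 0L
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    p <- ctx$profile
    if (is.null(p$poc)) next
    in_ml <- p$depth <= ctx$mld
    poc_ml <- mean(p$poc[in_ml], na.rm = TRUE)
    chl_ml <- mean(p$chlorophyll[in_ml], na.rm = TRUE)
    if (!is.finite(poc_ml) || !is.finite(chl_ml)) next
    if (chl_ml < chl_floor) { excluded <- excluded + 1L; next }
    ratios[i] <- poc_ml / chl_ml
  }
  ok <- is.finite(ratios)
  if (!any(ok)) {
    stop("no profile with valid POC and chlorophyll in the mixed layer")
  }
  out <- mean(ratios[ok])
  attr(out, "n") <- sum(ok)
  attr(out, "n_excluded") <- excluded
  out
}

#' POC from particulate backscattering
#'
#' Linear conversion `POC = slope * bbp700 + intercept`, used only when
#' POC is absent from the input. Coefficients are configurable; defaults
#' are of the order reported for Southern Ocean bbp-POC relations.
#'
#' @param bbp700 Backscattering at 700 nm, m-1 (>= 0 where valid).
#' @param slope ug C l-1 per m-1.
#' @param intercept ug C l-1.
#' @return POC per depth, ug C l-1 (NA where bbp is invalid or negative).
#' @export
poc_from_bbp <- function(bbp700, slope = 31200, intercept = 3.0) {
  out <- slope * bbp700 + intercept
  out[!is.finite(bbp700) | bbp700 < 0] <- NA_real_
  out
}
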