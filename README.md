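# phytofate

Partitioning the fate of Southern Ocean sea-ice-zone phytoplankton
blooms — downward phytodetritus export, total POC export, grazing,
mortality and biomass accumulation — from biogeochemical profiling-float
time series (temperature, salinity, nitrate, chlorophyll, POC).

**Who it is for:** biological oceanographers working with BGC-Argo-style
profile series in seasonally ice-covered waters, and anyone who wants a
fully testable implementation of the nitrate-drawdown loss budget with a
synthetic float whose every flux is known.

## The method in brief

Winter deep mixing resets upper-ocean nitrate to its deep value. During
the bloom, the salinity-normalized drawdown relative to the closest
winter profile, times a chl:N synthesis ratio *r* (reference 1.75 µg chl
per µmol N), gives the *potential* chlorophyll:

```
chl*(z)      = r · ΔNO3(z)                 ΔNO3 = NO3n,winter − NO3n
losses(z)    = chl*(z) − chl(z)            (chl quenching-corrected)
total        = ∫₀¹⁷⁵ max(0, losses) dz
phyto        = ∫_ed¹⁷⁵ max(0, −losses) dz  (ed = export depth)
local        = total − phyto               (⇒ total = local + phyto)
export flux  = c · Δ⁺phyto / Δt
grazing flux = c · Δ⁺local / Δt − mortality
```

with the export depth the deeper of the mixed-layer depth (0.01 kg m⁻³
density threshold) and the euphotic depth, a 175-m export horizon (the
deepest winter mixed layer), an advection screen on consecutive profiles
(ΔS₅₀₀ ≤ 0.05, Δlat ≤ 5.5°, Δlon ≤ 8°), three admissibility criteria
for grazing, and three chlorophyll-to-carbon conversions *c* (fixed
20 µg C/µg chl lower bound, a power law, or the float's mixed-layer
POC:chl ratio). The methods vignette
(`vignettes/phytoplankton-fate-partitioning.Rmd`) derives and justifies
every piece.

## Worked example

Simulate a matched, noise-free two-year float and invert it:

```r
library(phytofate)

cfg   <- pipeline_config(carbon_strategy = "fixed20")
quiet <- c(temperature = 0, salinity = 0, nitrate = 0,
           chlorophyll = 0, poc = 0, bbp700 = 0)
sim <- simulate_float(simulation_params(noise_sd = quiet,
                                        npq_artifact = FALSE, seed = 7),
                      cfg)
budgets <- series_budgets(sim$series, cfg)

annual <- sapply(c(grazing       = "grazing_flux",
                   phytodetritus = "phytodetritus_export_flux",
                   poc           = "poc_export_flux"),
                 function(t) as.numeric(annual_average(budgets, t)))
round(annual, 1)
#>       grazing phytodetritus           poc
#>          22.9           5.0          23.5
percent_grazed(annual[["grazing"]], annual[["phytodetritus"]])
#> [1] 82.12035

rec <- evaluate_recovery(sim$truth, budgets)
rec[, c("term", "n_defined", "mean_estimate", "mean_truth",
        "relative_bias")]
#>                   term n_defined mean_estimate mean_truth relative_bias
#> 1              grazing        34          22.9       22.8       0.00011
#> 2 phytodetritus_export        26           5.0        5.0      -0.00091
#> 3           poc_export        22          23.5       23.5       0.00000
#> 4            mortality        72           6.4        5.6       0.14790
#> 5         accumulation        18           5.4        5.2       0.02795
```

Reading the output: the pooled annual averages (mg C m⁻² d⁻¹) over all
defined pair estimates say that on this synthetic float grazing removes
22.9, phytodetritus export 5.0 and total POC export 23.5; grazing is
82% of the chlorophyll losses. `evaluate_recovery` compares each
estimate against the simulator's prescribed fluxes on the same
intervals: the inversion returns grazing and export to a fraction of a
percent. (The mortality row's bias comes from winter intervals where
the prescribed flux is zero but remnant phytodetritus sits inside the
deep winter mixed layer; it is exact wherever the flux is
non-negligible.)

`run_pipeline(series, cfg, "out/")` writes the per-pair budget table,
screen log, monthly and latitudinal box-plot climatologies, annual
averages and a metadata file echoing every configuration value;
`run_sensitivity()` re-runs the pipeline across chl:N ∈ {1.25, 1.75,
2.5}. A thin command-line wrapper with `simulate`, `convert`, `run` and
`sensitivity` subcommands is installed at `inst/scripts/phytofate`.

## File formats

* **CSV**: one row per (cycle, depth); columns `float_id, cycle, time
  (ISO-8601 UTC), latitude, longitude, under_ice, depth, temperature,
  salinity, nitrate, chlorophyll, poc, bbp700`. Optional variables that
  were never measured are omitted; invalid values are `NA`, never
  sentinels.
* **NetCDF**: Argo-like `N_LEVELS × N_PROF` layout (`TEMP`, `PSAL`,
  `NITRATE`, `CHLA`, `POC`, `BBP700`, `DEPTH`, `TIME`, position
  variables) with units attributes.

Both round-trip bit-comparably for finite values, and real
SOCCOM-derived profiles exported to either dialect are accepted as-is.

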