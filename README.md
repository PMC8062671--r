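# firescape

Spatio-temporal pattern analysis of wildfire event catalogs.

Wildfire burned areas are heavy-tailed: most fires are small, but the few
percent of large events dominate the total area burned, and fire managers
need to know *which* size law governs the tail, *where* ignitions
concentrate, *when* the season peaks, and *which* environmental and human
covariates drive ignition risk. firescape packages that analysis for
anyone working with point-based fire records (ignition coordinates,
discovery date, burned area in acres, cause code):

* **Fire-size distributions** — maximum-likelihood fits of gamma,
  lognormal, Pareto (Type I, closed-form Hill estimator), upper-truncated
  Pareto (conditional MLE, `H` at the sample maximum) and Weibull laws,
  ranked by AIC, Kolmogorov–Smirnov and Cramér–von Mises statistics.
* **Large-fire threshold** — mean excess curves
  `e(u) = E[X − u | X > u]` with automated change-point selection of the
  onset of tail linearity.
* **Temporal trends** — zero-filled annual frequency/burned-area series,
  segmented OLS around a fixed breakpoint (default 2000), monthly
  seasonality profiles and peak-month detection.
* **Hot-spot maps** — burned-area-weighted quartic kernel density
  `f(x) = (1/R²) Σ (3/π) Pᵢ (1 − (dᵢ/R)²)²` on raster grids (500 m
  default), with quantile density classes and ESRI ASCII grid I/O.
* **Ignition risk** — raster correlation screening (drop one of each pair
  with |r| > 0.5), PCA of the retained covariates, and logistic
  regression `ln(P/(1−P)) = w₀ + Σ wⱼxⱼ` of ignition presence on 3-km
  grid cells.
* **Synthetic data** — seeded generators for fire catalogs, Gaussian
  random-field covariate stacks and logistic presence grids, so the full
  pipeline runs and is tested without any external downloads.

## Worked example

Generate the canonical two-decade synthetic catalog, apply the database
minimum-size rule, and compare size laws:

```r
library(firescape)

cfg   <- california_like_config(seed = 2020)
catal <- filter_catalog(gen_catalog(cfg), min_size_rule = TRUE)
n_fires(catal)
#> [1] 4371

cmp <- compare_families(catal$records$size)
cmp[, c("family", "shape", "scale", "aic", "ks", "cvm")]
#>             family  shape     scale   aic     ks    cvm
#> 1        lognormal 5.3899 1.905e+00 65161 0.1050  14.34
#> 2 truncated_pareto 0.2846 1.002e+01 65472 0.1820  50.02
#> 3           pareto 0.3241 1.002e+01 65714 0.2043  64.82
#> 4          weibull 0.4025 6.293e+02 67531 0.1747  51.80
#> 5            gamma 0.2150 3.328e-05 70904 0.3235 158.17
```

The lognormal ranks first on all-sizes data — the body of the catalog is
lognormal by construction — with the Pareto pair next, carried by the
heavy tail. Shape values below one for the Pareto laws signal a tail so
heavy its mean is infinite, which is why large-fire totals are dominated
by a handful of events:

```r
sp <- split_by_size(catal, 500)
c(freq_share = 100 * n_fires(sp$large) / n_fires(catal),
  area_share = 100 * sum(sp$large$records$size) / sum(catal$records$size))
#> freq_share area_share
#>      22.79      98.22

peak_month(monthly_profile(catal, "frequency"))
#> [1] 7
```

About a fifth of fires are large (≥ 500 acres) yet they account for ~98%
of the burned area, and the season peaks in July. Hot-spot surfaces and
the gridded risk model come from the same catalog:

```r
ras <- kernel_density(catal, kde_params(search_radius = 25000,
                                        cell_size = 2000,
                                        weight_mode = "burned_area"))
write_ascii_grid(classify_density(ras, 5), "hotspots.asc")

res <- run_pipeline(pipeline_config(scenario = cfg, out_dir = "out",
                                    seed = 2020))
```

`run_pipeline()` chains every stage (catalog → size fits → threshold →
trends → KDE maps → correlation screen → PCA → logistic fit) and writes
CSV tables, ASCII rasters and a provenance manifest; identical config and
seed give byte-identical outputs. A thin CLI with the same stages as
subcommands (`simulate`, `fit-sizes`, `trends`, `kde`, `risk`,
`run-all`) is installed under `inst/exec/firescape`.

## Documentation

The methods vignette (`vignettes/firescape-methods.Rmd`) describes the
models and their assumptions, the estimators and their edge cases, the
synthetic-data generator's design and its limits, and the numerical
choices (tolerances, tie-breaks, degenerate inputs) in detail.
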