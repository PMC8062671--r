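---
title: "Methods: heavy-tailed fire sizes, hot-spot mapping and ignition risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heavy-tailed fire sizes, hot-spot mapping and ignition risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescape)
```

firescape analyses wildfire event catalogs — one record per ignition, with
projected coordinates, a year/month date, a burned area in acres and a raw
cause code — along four axes: the probability law of fire sizes, temporal
trends and seasonality, spatial hot-spot structure, and multivariate
ignition risk. This vignette explains the models, the assumptions behind
them, the tunable parameters, and the choices made where the design was
genuinely open.

## The fire catalog

Records carry a closed cause vocabulary: `lightning` (the only natural
cause), fifteen anthropogenic codes grouped into transportation
(railroad, vehicle, aircraft), human activity (equipment use through
illegal campfire) and construction (powerline, structure), plus
`miscellaneous` and `unknown`. The raw-code-to-group mapping ships as a
versioned CSV in `inst/extdata/` so the grouping is data, not code.

Dates are stored at month precision: the analyses aggregate by year and
month only, so a day component carries no information here. Coordinates
are assumed already projected in metres; the CRS is recorded as an opaque
tag and no geodesy is performed. Statewide fire-perimeter databases only
admit fires above fuel-dependent minima — 10 acres for timber, 30 for
brush, 300 for grass — and `filter_catalog(min_size_rule = TRUE)` applies
the same rule so synthetic and real catalogs are comparable. Areas
convert with the international acre, 1 acre = 0.0040468564224 km²,
exactly.

Large fires are defined by `size >= threshold`: the threshold itself is a
*large-fire* size, consistent with class-based size taxonomies where a
class is "of or larger than" its lower bound.

## Fire-size laws and their estimators

Burned areas are strongly heavy-tailed: most fires are small, while a few
percent of events dominate the total area burned. Five candidate laws are
fitted by maximum likelihood (`fit_distribution()`):

| family | density | shape | scale |
|---|---|---|---|
| gamma | $\beta^{\alpha}/\Gamma(\alpha)\, x^{\alpha-1} e^{-\beta x}$ | $\alpha$ | rate $\beta$ (acre$^{-1}$) |
| lognormal | $\tfrac{1}{\sqrt{2\pi}\,\beta x} e^{-(\ln x-\alpha)^2/2\beta^2}$ | log-mean $\alpha$ | log-sd $\beta$ |
| Pareto (Type I) | $\alpha\beta^{\alpha} x^{-\alpha-1}$, $x \ge \beta$ | $\alpha$ | $\beta$ (acres) |
| truncated Pareto | $\dfrac{\alpha\beta^{\alpha} x^{-\alpha-1}}{1-(\beta/H)^{\alpha}}$, $\beta \le x \le H$ | $\alpha$ | $\beta$; bound $H$ |
| Weibull | $\tfrac{\alpha}{\beta}(x/\beta)^{\alpha-1}e^{-(x/\beta)^{\alpha}}$ | $\alpha$ | $\beta$ (acres) |

The Pareto MLE is closed form (the Hill estimator): $\hat\beta = \min x$,
$\hat\alpha = n / \sum \ln(x_i/\hat\beta)$. The truncated Pareto uses the
conditional MLE with $H$ fixed at the sample maximum and $\hat\alpha$
solved from the score equation by bisection to tolerance $10^{-10}$. Two
numerical notes:

* On samples that are very un-Pareto-like (e.g. strongly lognormal
  bodies) the conditional likelihood can be maximised at the
  $\alpha \to 0$ boundary, whose limit is the log-uniform distribution.
  There is then no interior MLE; `fit_distribution()` raises a typed fit
  error and `compare_families()` records the failure without aborting the
  other families.
* Gamma and Weibull likelihoods are maximised via `fitdistrplus` on
  scale-normalised data ($x/\bar x$), with estimates and log-likelihood
  mapped back exactly. Burned areas span six orders of magnitude and this
  keeps the optimiser conditioned.

A shifted-Pareto (Lomax) variant is available behind `family = "lomax"`
for sensitivity analysis, because fitted Pareto scale parameters reported
in the literature sometimes suggest a shifted convention; the Type I form
with the density above is the reference parameterization everywhere in
this package.

Fitting on the log of size (`log_transform = TRUE`, gamma / lognormal /
Weibull only) supports the usual log-size view of the distribution.

### Goodness of fit

`goodness_of_fit()` scores a fit with three criteria, all
smaller-is-better: AIC $= 2k - 2\hat\ell$ with $k = 2$ free parameters
($H$ is fixed at the sample maximum, hence not counted); the
Kolmogorov–Smirnov statistic
$\max_i \max(|i/n - F(x_{(i)})|, |(i-1)/n - F(x_{(i)})|)$; and the
Cramér–von Mises statistic
$\tfrac{1}{12n} + \sum_i \big(\tfrac{2i-1}{2n} - F(x_{(i)})\big)^2$.
Statistics are evaluated against the fitted CDF without
estimated-parameter (bootstrap) calibration, so they are comparison
scores, not calibrated p-values — which is all the family ranking needs.

### The large-fire threshold

The mean excess function $e(u) = E[X - u \mid X > u]$ is linear in $u$
for a generalized-Pareto tail, and the onset of linearity marks the
threshold where tail behaviour begins. Because reading that onset off a
plot is subjective, `select_threshold()` automates it with an exhaustive
two-segment least-squares change-point fit over a candidate grid: each
candidate splits the curve, a line is fitted to each side, and the
candidate minimising total RSS wins, with ties (at a tolerance relative
to the curve's total variation) broken to the smallest candidate. An
exactly linear curve therefore returns the smallest candidate, and a
flat-then-linear curve returns the kink. The curve is truncated where
fewer than `min_exceedances` (default 30) observations remain, since tail
means over a handful of points are noise.

## Temporal trends

`annual_series()` zero-fills years with no fires so that trend
regressions see the full calendar span, and `segmented_regression()` fits
independent OLS lines before and at/after a fixed breakpoint (default
2000). No continuity is imposed at the join — the two periods are
treated as separate regimes, and the breakpoint is a parameter, not
estimated. Reported confidence bands are 95% mean-prediction bands.
Seasonality uses per (month, year) totals; `peak_month()` maximises the
across-year mean with ties to the earlier month, and `season_span()`
implements a descriptive rule (months above half the peak mean) that is
reporting convenience, not inference.

## Hot-spot mapping

`kernel_density()` evaluates the weighted quartic (biweight) kernel
density at every cell centre of a raster:

$$f(x) = \frac{1}{R^2} \sum_{i\,:\,d_i < R} \frac{3}{\pi} P_i
  \left(1 - (d_i/R)^2\right)^2,$$

where $R$ is the search radius, $d_i$ the point-to-cell distance and
$P_i$ the per-point weight — 1 for occurrence density, the burned area
for area-weighted density. The kernel integrates to one, reaches exactly
zero at $R$, and densities are per m². The raster extent pads the point
bounding box by $R$ so no kernel is clipped; no edge correction is
applied. The default resolution is 500 m.

The search radius is a free parameter. When not supplied it comes from
the standard point-pattern rule of thumb
$R = 0.9\,\min(SD_w, \sqrt{1/\ln 2}\, D_m)\, n_\mathrm{eff}^{-1/5}$ with
the weighted standard distance, weighted median distance and the Kish
effective sample size $(\sum w)^2/\sum w^2$ — deterministic and
scale-equivariant. Tests pin $R$ explicitly.

Hot-spot class maps (`classify_density()`) use quantile classes of the
nonzero cells with order-statistic quantiles (type 1), making the class
map invariant under monotone transforms of the density. Rasters are
exchanged as ESRI ASCII grids — a plain-text format that round-trips
exactly at the stored precision.

## Ignition-risk analysis

The multivariate stage works on a stack of co-registered covariate
rasters (distances to roads and powerlines, housing and population
density, elevation, slope, aspect, tree/shrub/grass cover, maximum
temperature, maximum vapour pressure deficit).

1. **Correlation screen.** `raster_correlation()` computes pairwise
   Pearson correlations over cells with the $N-1$ covariance.
   `filter_correlated()` then removes variables greedily until no
   off-diagonal $|r|$ exceeds the threshold (default 0.5): at each step
   the variable with the largest mean $|r|$ among the violating ones is
   dropped, unless it is protected by a `keep_rules` preference list.
   The preference list mirrors the manual practice of choosing one
   variable of each correlated pair on subject-matter grounds (road
   distance over powerline distance, housing over population, climate
   over elevation).
2. **PCA.** `pca_covariates()` eigendecomposes the correlation matrix by
   default — the variables span incommensurate units (km, houses/km²,
   degrees, %, °C, hPa), so covariance-scale PCA would be dominated by
   whichever variable has the largest numeric variance. Component signs
   follow a deterministic convention (largest-magnitude loading
   positive).
3. **Gridded logistic regression.** `grid_aggregate()` divides the
   window into square analysis cells (default 3 km), flags a cell
   present if any ignition point falls in its half-open rectangle
   $[x, x+s) \times [y, y+s)$ (a partition, so no point counts twice),
   and averages each covariate over the stack cells whose centres fall
   inside. `logistic_fit()` then fits
   $\ln\!\big(P/(1-P)\big) = w_0 + \sum_j w_j x_j$ by IRLS with Wald
   standard errors. Separation and non-convergence are flagged, never
   swallowed. No spatial autocorrelation correction is applied — the
   model is deliberately the plain logistic regression of the gridded
   design.

## The synthetic-data generator

Every stage is testable without downloads because `gen_catalog()`,
`gen_covariate_stack()` and `gen_presence_grid()` draw from a fully
specified scenario (`synthetic_config()`), reproducibly per seed.
Sub-streams are derived per component with fixed offsets, so adding a
generator never changes the draws of another.

The canonical scenario (`california_like_config()`) encodes the study
conditions the package assumes for a recent two-decade statewide record:

* 5234 fires over 2000–2019 in a 600 km square window with three
  Gaussian ignition hot spots;
* a spliced size law: truncated-lognormal body (log-mean 4.79, log-sd
  1.83) on [10, 500) acres, truncated-Pareto tail at or above 500 acres
  with shape 0.482, tail mass 0.1968. The tail must be *truncated*
  (ceiling 1.3 million acres, the scale of the largest recorded
  statewide fires): a shape below one has infinite mean, so an
  untruncated tail would make burned-area totals unstable;
* the published two-decade cause mix and a July-peaked month profile;
* twelve Gaussian-random-field covariates (white noise smoothed to each
  variable's correlation length, cross-correlated by Cholesky mixing:
  roads–powerline 0.55, housing–population 0.81, elevation–Tmax −0.84,
  elevation–VPDmax −0.61, Tmax–VPDmax 0.60);
* the published logistic coefficient vector, with the intercept set so
  the expected presence rate matches the published share of burned cells
  (≈ 7.05%), accounting for the variance of the linear predictor.

What the generator does *not* emulate: real California geography and
coastlines, agency unit boundaries, spatially varying seasonality,
fire-spread dependence between events (records are i.i.d. given the
scenario), and covariate fields with realistic non-Gaussian marginals
(distances are Gaussian fields, not true distance transforms). Passing
tests therefore demonstrate that the estimators recover known structure
under the stated stochastic model — not that any particular real
catalog follows that model.

A note on the threshold-selection check: the mean-excess change-point
scenario grafts a Pareto tail with shape 2 (finite mean, mean-excess
slope 1) at 500 acres, rather than the canonical 0.482 tail. An
infinite-mean tail has no stable empirical mean excess, so it cannot
carry a slope-based recovery check; the shape-2 graft tests the same
detector under conditions where the diagnostic is defined.

## Problem sizes and numerical choices

The test-suite and verification-script simulations use: n = 5234 for
size-law recovery (the two-decade catalog size), n = 5000 × 50 replicates
for AIC model-selection consistency, ~50,000 3-km cells for logistic
recovery, 20,000 fires for the spliced-threshold scenario, and reduced
rasters (10–12 km cells) for pipeline-level checks — sizes chosen to make
Monte-Carlo error small relative to the tolerances tested while keeping a
full run in the tens of seconds. Tolerances follow the quantity: exact
arithmetic is asserted at the printed precision, simulation recoveries at
three standard errors (Monte-Carlo or Wald), and mass conservation of the
kernel at 1% with cells of R/10.

Known limitations: no bootstrap calibration of goodness-of-fit
statistics; no autocorrelation-aware trend tests; no adaptive-bandwidth
or edge-corrected KDE; raster exchange is ASCII-grid only; and the
truncated-Pareto conditional MLE deliberately reports failure (rather
than a boundary estimate) when no interior maximum exists.
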