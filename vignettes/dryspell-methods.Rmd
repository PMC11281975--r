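---
title: "Methods: growth and greenness responses to dry spells"
author: "dryspell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth and greenness responses to dry spells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryspell)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters and the
numerical decisions. The companion synthetic-data module is described
last, together with what passing the test suite does and does not
demonstrate about real data.

## 1. Tree-ring detrending and chronologies

Ring-width series mix an age-related decline, slow stand dynamics and the
interannual climate signal of interest. `spline_detrend()` removes the
slow part with a stiffness-penalized smoothing spline: the fitted curve
$z$ minimizes $\sum_i (w_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$
over the observed years. On an annual grid this smoother has amplitude
frequency response $H(f) = 1/(1 + \lambda\,(2\sin \pi f)^4)$, so setting

$$\lambda = \big(2 \sin(\pi / P)\big)^{-4}$$

makes $H = 0.5$ exactly at the cutoff period $P$ (default
`wavelength_years = 30`). This is the classical dendrochronological
"50 % frequency cutoff" spline: a 30-year sinusoid is attenuated by half,
faster variation passes into the index, slower variation is removed. The
acceptance script measures the realized attenuation on a 330-year
sinusoid; the test suite additionally checks monotonicity of the response
at periods 10/30/100 years and agreement with an independent dense solve
of the penalized system (max abs difference < 1e-8).

Numerical choices:

* **Missing rings** are represented as `NA` gaps, excluded from the fit;
  the penalty uses second *divided* differences so the remaining years
  keep a consistent stiffness across a gap. Tucson files encode a gap as
  the value 0 (read back as `NA`, never as a zero width).
* **Tree-ring index**: `tri = width / fitted`, dimensionless with
  long-run mean near 1. A non-positive fitted value is an error by
  default; `on_nonpositive = "mean"` falls back to horizontal-mean
  detrending for that series.
* A smoothing spline reproduces exactly only the penalty null space
  (linear trends). A pure negative-exponential age curve is therefore
  tracked, not interpolated: noise-free synthetic series detrend to an
  index within 0.01 of 1 everywhere (0.005 away from the series ends),
  and the tests assert exactly that, not exact unity.
* **Series length**: at least `wavelength/2` observed rings are required;
  shorter series are rejected.

`build_chronology()` averages tree-level indices year by year with
Tukey's biweight robust mean (tuning constant 9 × MAD about the median,
fixed-point iteration, at most 10 iterations or relative change < 1e-6,
median fallback when the MAD is zero) and records the sample depth. Years
with fewer than `min_depth = 5` trees are dropped; the robust mean keeps
single anomalous trees (rot, damage, measurement slips) from distorting
the plot signal.

## 2. Growing-season NDVI series

`compute_ndvi()` is the usual normalized difference
$(\mathrm{NIR}-\mathrm{Red})/(\mathrm{NIR}+\mathrm{Red})$; a zero
denominator yields `NA`. The annual value of a plot is built in four
steps:

1. **Thermal season window** (`growing_season_window()`): the season
   opens on the first day of year $d \ge 6$ whose five *preceding* days
   (d−5 … d−1) have mean temperature strictly above the species
   threshold — 12 °C for pine, 9 °C for spruce, the bud-burst triggers
   for these species at comparable elevations — and closes on
   30 September. We interpret the end as the calendar date: day-of-year
   274 in leap years, 273 otherwise. If no day qualifies the season is
   empty and flagged.
2. **Median composite** (`annual_median_composite()`): per pixel, the
   median NDVI over unmasked scenes inside the window; even counts
   average the two middle values. NDVI is computed per scene first and
   the median taken afterwards. Pixels with no usable observation
   propagate `NA`.
3. **Overlap weighting** (`extract_plot_value()`): plot value = weighted
   mean of pixel composites, weights proportional to the plot area
   falling in each pixel, renormalized over non-missing pixels.
4. **Linear detrending** (`detrend_linear_residuals()`): an OLS line of
   NDVI on calendar year absorbs slow drifts (canopy densification, CO2
   fertilization); the residuals are the greenness anomalies used
   downstream. At least 3 non-missing years are required.

## 3. Drought indices and event selection

`thornthwaite_pet()` implements the classical temperature-based monthly
potential evapotranspiration: heat index $I=\sum (T_m/5)^{1.514}$ over
positive months, exponent $a = 6.75\times10^{-7}I^3 - 7.71\times10^{-5}
I^2 + 1.792\times10^{-2} I + 0.49239$, $\mathrm{PET} = 16\,(10T/I)^a$ mm
per standard month with the hot-month polynomial above 26.5 °C, then the
day-length/month-length correction $(N/12)(d/30)$. PET is zero at or
below freezing.

`spei()` accumulates the water balance $D = P - \mathrm{PET}$ over a
window of `scale = 4` months ending in (and including) the current month
— our reading of a "4-month" drought index — fits a three-parameter
log-logistic distribution per calendar month by unbiased
probability-weighted moments over the calibration years, and maps the
fitted CDF through the standard-normal quantile (`qnorm`, exact). Two
numerical points:

* Left-skewed balance samples produce a negative fitted shape; that is
  the *reflected* (upper-bounded) log-logistic, still a valid CDF, and is
  accepted as long as $|\beta| > 1$ (mean exists). Values outside the
  support saturate at CDF 0 or 1, clamped to ±`qnorm(1e-6)`.
* At least 20 calibration values per calendar month are required, and a
  constant accumulated series is an error naming the month.

Seasonal series are plain arithmetic means over June–August (JJA) or
May–September (GS). `severity_anomalies()` subtracts the baseline mean
and by default divides by the baseline SD: severities are then unitless,
making mixed-model coefficients comparable across climate variables
(raw-unit anomalies remain available with `standardize = FALSE`). The
baseline defaults to the full analysis window (1985–2017 in the default
design), which is also the SPEI calibration period.

`select_drought_years()` picks the `n = 4` most severe *non-consecutive*
years greedily: repeatedly take the most extreme remaining year whose
neighbours (±1 year) are unselected, ties toward the earlier year.
Non-consecutiveness avoids confounding an event's lagged response with
the next event. Greedy selection is our choice where only the intent is
fixed; the tests verify it attains the enumeration optimum on the
documented worked example.

## 4. Superposed epoch analysis

`superposed_epoch()` reports, for lags −4…+4, the mean of the series over
event years shifted by the lag minus the overall series mean — the
common SEA convention for the reference level. Significance is empirical:
`resamples = 1000` random event sets of the same size are drawn uniformly
without replacement from the years whose full window fits, by default
preserving the non-consecutiveness of real event sets (the sampling frame
should match the statistic), and the two-sided p-value is
$(1 + \#\{|d^*| \ge |d|\})/(R+1)$, floored away from zero. Events whose
window is truncated by the series edge are dropped with a warning.

Note one interaction with detrending: events spaced a few years apart
(2003 and 2006 in the default design) form a broader depression that the
30-year spline partially absorbs, slightly inflating the index *between*
clustered events. The recovery tests therefore compare the noisy pipeline
against a noise-free reference run of the identical design (which is
deterministic and carries the same absorption), and separately check that
the reference stays within 0.05 of the pure closed-form departures.

`climate_growth_correlations()` provides the Pearson screen (current and
previous year, t-distribution p-values with $n-2$ df) used to decide
which climate variable drives event selection.

## 5. Mixed models, metrics, resilience

`build_response_table()` assembles one row per plot × event × lag
(lags 0–4): the response (chronology index, or NDVI residuals
standardized per plot to mean 0, SD 1 — our definition of "scaled"
NDVI), the event-year severity SEV0 and the row-year severity SEV. At
lag 0 SEV equals SEV0 by the row-year convention (`sev_lag0 = "zero"`
gives the alternative). Rows whose lag year leaves the series are
omitted.

`lmm_ri()` fits $y = X\beta + Zb + \varepsilon$ with a single random
intercept (plot category) by REML. The criterion is profiled to one
dimension: for a given variance ratio $\gamma = \sigma_b^2/\sigma^2$ the
block structure $(I + \gamma \mathbf{1}\mathbf{1}^\top)^{-1}$ gives
closed-form GLS estimates from group-level sufficient statistics, and
$-2\,l_R(\gamma) = (n-p)\{\log 2\pi\hat\sigma^2 + 1\} + \sum_g \log(1 +
n_g\gamma) + \log|X^\top V_0^{-1}X|$ is minimized over $\log\gamma$ with
the boundary $\gamma = 0$ checked explicitly (reported as a singular
flag, not an error). The test suite verifies exact agreement with
`lme4::lmer` (REML log-likelihood, AIC, fixed effects, variances,
standard errors). AIC counts $p$ fixed effects plus both variance
components. Fixed-effect p-values use the large-sample normal reference;
`confint()` gives Wald intervals for $\beta$, a profile-REML interval for
$\sigma_b^2$ and a chi-square interval for $\sigma^2$.

`model_metrics()` reports the Nakagawa-style variance partition:
marginal $R^2 = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\hat\sigma_b^2 + \hat\sigma^2)$, conditional $R^2$ adding
$\hat\sigma_b^2$ to the numerator, pseudo-$R^2$ as the squared
correlation of observed and fitted values (group effects included), and
a numerical q-q check (correlation of sample vs theoretical normal
quantiles of the residuals) in place of a visual plot. `vif()` is the
textbook $1/(1-R^2)$ from regressing each predictor on the rest.
`random_effect_lrt()` compares REML log-likelihoods with and without the
random intercept on identical rows and refers $2\Delta l_R$ (floored at
0) to $\chi^2(1)$ — matching the conventional `ranova` behaviour; with
the true variance on the boundary this reference is conservative, which
we accept for comparability.

`resilience_metrics()` computes the Lloret ratios with 3-year pre/post
windows (the common convention): resistance = event/pre, recovery =
post/event, resilience = post/pre, so resilience = resistance × recovery
is an exact identity. Other event years can be excluded from the
windows.

## 6. The synthetic-data module

`simulation_config()` fixes the study design the analysis assumes:
33 years (1985–2017), two species × 20 plots in four topographic
categories of five plots, at least 26 trees per plot, and four injected
non-consecutive drought years (1994, 2003, 2006, 2015). Remaining
defaults are our choices of realistic magnitudes, made once:

* **Climate.** Daily temperature: 7 °C mean, 10 °C annual sinusoidal
  amplitude, 2 °C daily noise (mid-elevation Central Europe); monthly
  precipitation/solar-radiation/soil-moisture follow seasonal cycles with
  Gaussian noise. Drought years add `sr_anomaly = 2` baseline SDs to each
  JJA month's solar radiation *on top of folded (non-negative) noise* —
  so the realized anomaly is at least the configured one, as befits years
  defined as extremes — depress soil moisture symmetrically, add 1.5 °C
  to summer days and halve summer precipitation, making the dry spells
  visible in every variable and in SPEI.
* **Rings.** Negative-exponential age curve $w(a) = A e^{-a/\tau} + c$
  (per-tree $A \in [2,4]$ mm, $\tau \in [40,80]$ y, $c \in [0.3,0.8]$ mm,
  tree ages ~N(113, 15) years as in mature stands), multiplied by a
  fractional climate coupling (−0.03 per SD of JJA radiation, +0.03 per
  SD of JJA soil moisture), the event-year drop `growth_drop = 0.2`, the
  legacy vector (0.10, 0.05, 0, 0) over lags 1–4 — strong suppression for
  two post-drought years, consistent with multi-year legacy effects — and
  mean-one lognormal AR(1) noise (SD 0.2, AR 0.3), keeping widths
  strictly positive.
* **Scenes.** Per plot a 2 × 2 pixel neighbourhood with overlap weights
  (0.4, 0.3, 0.2, 0.1) stands in for the 16 m plot vs 30 m pixel
  geometry; per-pixel NDVI = 0.75 base + 0.002/yr drift + a 0.05
  within-season bell + event dip 0.04 + lag-1..2 rebound 0.015 + fixed
  small pixel offsets + Gaussian AR(1) noise (SD 0.02), clamped to
  [−1, 1] (clamps counted), converted to red/NIR at a fixed total
  reflectance of 0.5, with each pixel-date cloud-masked with probability
  0.2. The generator records the true per-pixel growing-season median
  NDVI as ground truth.

Everything is deterministic under the configuration seed (each generator
uses its own derived sub-seed, so the three can be called independently).

**What this does and does not show.** The generator reproduces the
statistical *structure* the pipeline assumes — age trends, climate
coupling, event effects with legacies, phenology-windowed greenness with
clouds — so passing tests demonstrate that every stage recovers known
inputs at realistic noise levels. It does not emulate cross-sensor
differences, atmospheric effects, spatial autocorrelation between plots,
within-plot competition, topographic microclimate (the categories carry
no injected effect, so random-intercept variances are genuinely near
zero here), event-to-event severity variation (all drought years are
injected at the same anomaly, which leaves SEV0 with little variance in
pipeline-level model fits), or within-plot tree-age structure beyond
random ages. Conclusions about real data still require the real data.

## 7. Problem sizes and runtime choices

The default pipeline (2 × 20 plots, 26 trees/plot, 33 years, 1000 SEA
resamples) runs in well under a minute on one CPU. The test suite keeps
simulation-based checks at deliberately modest sizes — 200 replicates for
mixed-model recovery, AIC ordering and LRT calibration, 500 replicates
for the SEA type-I error (300 resamples each), 2000 replicates for
correlation calibration, reduced plot/tree counts in pipeline tests —
sizes at which the asserted tolerances are comfortably resolved by the
binomial/Monte-Carlo error of the check itself.

## 8. Known limitations

* The spline smoother is the discrete (annual-grid) penalized form; its
  response is exact on the infinite grid and approximate near series
  ends, hence the boundary allowance in the noise-free detrending test.
* SPEI distribution fitting with 33 values per calendar month is noisy;
  the standardization test tolerances (mean ±0.05, SD ±0.1) reflect
  that, not a defect.
* Only a single random intercept is supported (no nested/crossed
  effects), p-values are large-sample, and no Kenward–Roger or
  Satterthwaite correction is attempted.
* Event selection is greedy; it matches exhaustive search on the tested
  configurations but is not guaranteed optimal for adversarial severity
  patterns.
* The season-end rule treats "30 September" as a calendar date; sources
  quoting it as day-of-year 274 implicitly assume a leap year.
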