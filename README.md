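# dryspell

Quantifying how conifer stem growth and canopy greenness respond to
extreme dry spells.

Temperate conifer stands (Scots pine *Pinus sylvestris*, PISY; Norway
spruce *Picea abies*, PCAB) respond to hot droughts both in wood formation
and in leaf activity, and the two responses need not coincide. `dryspell`
implements the full statistical chain used to compare them on plot
networks spanning contrasting topographic settings (south slope, north
slope, plateau, valley):

* **Tree-ring indices (TRI).** Ring-width series are detrended with a
  cubic smoothing spline whose stiffness is set by a *50 % frequency
  cutoff at 30 years*: the fitted curve retains half the amplitude of a
  30-year sinusoid, so the age trend and slower variation are removed
  while interannual variability is kept. TRI = observed / fitted width,
  and plot chronologies are Tukey biweight robust means of the tree-level
  indices. Tucson (RWL) files are read and written natively.
* **Canopy greenness (NDVI).** Per-scene NDVI = (NIR − Red)/(NIR + Red)
  from Landsat-style red/NIR reflectances with cloud masks. Scenes are
  restricted to a thermal growing season — starting the first day whose
  five preceding days average above 12 °C (PISY) or 9 °C (PCAB), ending
  30 September — composited to per-pixel annual medians,
  overlap-weighted to plot values, and linearly detrended to residuals.
* **Drought indexing.** Thornthwaite potential evapotranspiration,
  4-month SPEI (probability-weighted-moment log-logistic fit per calendar
  month), June–August (JJA) and May–September (GS) seasonal means, and
  standardized severity anomalies. The most severe *non-consecutive*
  drought years are selected greedily from the summer solar-radiation
  (or soil-moisture) severities.
* **Superposed epoch analysis (SEA).** Mean departures of a series at
  lags −4…+4 around the drought years, with two-sided significance from
  ≥1000 random non-consecutive event sets.
* **Mixed models and resilience.** TRI or scaled NDVI in the drought year
  and four following years is modelled as `response ~ SEV0 + SEV` with a
  plot-category random intercept, where SEV0 is the event-year
  solar-radiation severity and SEV the row-year severity. The
  random-intercept REML fit is profiled over the variance ratio and
  reports AIC, marginal/conditional R² (Nakagawa), pseudo-R², VIF and a
  `ranova`-style random-effect likelihood-ratio test. Lloret resilience
  metrics (resistance = event/pre, recovery = post/event, resilience =
  post/pre) complete the picture.
* **Synthetic data.** A first-class generator produces daily/monthly
  climate with injected high-radiation low-moisture drought years,
  age-trended ring widths with configurable lag-0 drops and 4-year
  legacies, and cloud-masked reflectance scenes with known ground truth —
  so every stage of the pipeline is testable end to end without any
  download.

## Worked example

A reduced synthetic study (8 plots per species, 10 trees per plot,
otherwise the default 1985–2017 design with drought years 1994, 2003,
2006, 2015):

```r
library(dryspell)
cfg <- pipeline_config(seed = 42, out_dir = tempfile(),
  simulation = simulation_config(seed = 42, n_plots_per_species = 8,
                                 trees_per_plot = 10))
res <- run_pipeline(cfg, quiet = TRUE)

res$events
#> Drought event set (SR, site): 1994, 2003, 2006, 2015
```

The event years are recomputed from the generated climate (highest
non-consecutive JJA solar-radiation severities) and recover the injected
drought years exactly. The first plot chronology:

```r
res$chronologies[[1]]
#> Plot chronology PI01
#>   years: 1985 - 2017  mean index: 0.995  mean depth: 10
```

SEA around the drought years for that plot (the injected lag-0 growth
drop is 0.2 of the ring width; the departure is relative to the series
mean, hence −0.27 including the plot's climate coupling):

```r
res$sea[res$sea$series_id == "TRI_PI01" & res$sea$lag %in% -1:2, ]
#>  series_id lag    departure           p
#>   TRI_PI01  -1  0.020063856 0.749250749
#>   TRI_PI01   0 -0.274775557 0.001998002
#>   TRI_PI01   1 -0.070550013 0.318681319
#>   TRI_PI01   2  0.003760668 0.966033966
```

Only the event-year departure is significant at the resampling null
(p = 0.002 at 1000 resamples). The severity models for PISY TRI:

```r
res$models[res$models$species == "PISY" & res$models$response == "TRI",
           c("variant", "AIC", "r2_marginal", "t_sev0", "t_sev", "ranef_p")]
#>       variant       AIC r2_marginal   t_sev0     t_sev   ranef_p
#>          full -297.7579  0.71521424 2.701544 -18.14661 0.9280959
#>  without_SEV0 -297.5115  0.70210382       NA -18.36604 0.9715560
#>   without_SEV -137.5926  0.06065019 3.038578        NA 1.0000000
```

Dropping SEV (the row-year severity, which carries the injected signal
here) collapses the explained variance, while the plot-category random
effect is negligible (`ranef_p` ≈ 1) — the generator injects no
topographic differences. All tables are also written as CSV/JSON to
`cfg$out_dir` together with a run manifest; a fixed seed gives
byte-identical outputs.

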