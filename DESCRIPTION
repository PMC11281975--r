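Package: dryspell
Title: Stem-Growth and Canopy-Greenness Responses of Conifers to Dry Spells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how conifer stem growth (tree-ring
    indices) and canopy greenness (Landsat-style NDVI) respond to extreme
    dry spells. Implements ring-width detrending with a 50 percent
    frequency-cutoff cubic smoothing spline and Tukey biweight plot
    chronologies, phenology-windowed annual NDVI compositing with linear
    detrending, Thornthwaite potential evapotranspiration and the
    standardised precipitation-evapotranspiration index (SPEI),
    non-consecutive drought-year selection, superposed epoch analysis with
    a resampling null, Lloret-type resilience metrics, and random-intercept
    linear mixed models fitted by restricted maximum likelihood with
    marginal and conditional R-squared, variance inflation factors and a
    random-effect likelihood-ratio test. A synthetic-data module generates
    climate, ring-width and reflectance-scene inputs with known injected
    drought effects so the whole pipeline can be exercised and validated
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, lme4, lmerTest, car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
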