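#' Configuration for the synthetic dry-spell dataset
#'
#' Collects every knob of the synthetic-data generators. The defaults
#' emulate the study design the analysis assumes: 33 years (1985-2017),
#' two conifer species (PISY = Scots pine, PCAB = Norway spruce) with 20
#' plots each, five plots in each of four topographic categories (south
#' slope SS, north slope NS, plateau PL, valley VA), at least 26 trees per
#' plot, and four injected non-consecutive drought years (1994, 2003,
#' 2006, 2015) with elevated summer solar radiation, depressed soil
#' moisture, a lag-0 growth drop and multi-year growth legacies, and an
#' NDVI dip followed by a rebound.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param years inclusive year range of the analysis window.
#' @param n_plots_per_species plots per species (spread over categories).
#' @param categories topographic category labels.
#' @param drought_years injected event years (pairwise non-consecutive).
#' @param sr_anomaly injected June-August solar-radiation excess in
#'   multiples of the baseline monthly SD (injected additively on top of
#'   folded noise, so the realized anomaly is at least this large).
#' @param growth_drop fractional ring-width reduction in the event year.
#' @param legacy fractional reductions in the four years after an event.
#' @param ndvi_drop growing-season NDVI reduction in the event year.
#' @param ndvi_rebound NDVI excess in the one to two years after an event.
#' @param ndvi_trend linear NDVI drift per year (canopy densification).
#' @param ring_ar,ring_sd AR(1) coefficient and stationary SD of the
#'   lognormal tree-level noise.
#' @param ndvi_ar,ndvi_sd AR(1) coefficient and SD of pixel-level NDVI
#'   noise.
#' @param cloud_fraction probability that a pixel-date is cloud-masked.
#' @param coupling_sr,coupling_sm fractional growth response per SD of the
#'   summer solar-radiation / soil-moisture anomaly.
#' @param trees_per_plot trees sampled per plot (>= 26).
#' @param latitude site latitude in degrees (for PET day length).
#' @param ndvi_base,ndvi_seasonal_amp base NDVI level and within-season
#'   amplitude.
#' @param species_thresholds named degC thresholds that open the thermal
#'   growing season.
#' @return object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              years = 1985:2017,
                              n_plots_per_species = 20L,
                              categories = c("SS", "NS", "PL", "VA"),
                              drought_years = c(1994L, 2003L, 2006L, 2015L),
                              sr_anomaly = 2,
                              growth_drop = 0.2,
                              legacy = c(0.1, 0.05, 0, 0),
                              ndvi_drop = 0.04,
                              ndvi_rebound = 0.015,
                              ndvi_trend = 0.002,
                              ring_ar = 0.3, ring_sd = 0.2,
                              ndvi_ar = 0.3, ndvi_sd = 0.02,
                              cloud_fraction = 0.2,
                              coupling_sr = -0.03, coupling_sm = 0.03,
                              trees_per_plot = 26L,
                              latitude = 49.5,
                              ndvi_base = 0.75, ndvi_seasonal_amp = 0.05,
                              species_thresholds = c(PISY = 12, PCAB = 9)) {
  years <- as.integer(years)
  drought_years <- sort(as.integer(drought_years))
  if (!all(drought_years %in% years)) {
    bad <- drought_years[!drought_years %in% years][1]
    stop("drought year ", bad, " lies outside the simulated year range")
  }
  if (length(drought_years) > 1 && any(diff(drought_years) <= 1)) {
    stop("drought years must be pairwise non-consecutive")
  }
  fr <- c(growth_drop, legacy, ndvi_drop, ndvi_rebound, cloud_fraction)
  if (any(fr < 0 | fr >= 1)) stop("all fractions must lie in [0, 1)")
  if (length(legacy) != 4) stop("legacy must give reductions for lags 1..4")
  cfg <- list(seed = as.integer(seed), years = years,
              n_plots_per_species = as.integer(n_plots_per_species),
              categories = categories, drought_years = drought_years,
              sr_anomaly = sr_anomaly, growth_drop = growth_drop,
              legacy = legacy, ndvi_drop = ndvi_drop,
              ndvi_rebound = ndvi_rebound, ndvi_trend = ndvi_trend,
              ring_ar = ring_ar, ring_sd = ring_sd,
              ndvi_ar = ndvi_ar, ndvi_sd = ndvi_sd,
              cloud_fraction = cloud_fraction,
              coupling_sr = coupling_sr, coupling_sm = coupling_sm,
              trees_per_plot = as.integer(trees_per_plot),
              latitude = latitude, ndvi_base = ndvi_base,
              ndvi_seasonal_amp = ndvi_seasonal_amp,
              species_thresholds = species_thresholds)
  class(cfg) <- "simulation_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Plot metadata table for a simulation configuration
#'
#' @param config a [simulation_config()].
#' @return data.frame with `plot_id`, `species`, `category`.
#' @export
simulate_plots <- function(config) {
  out <- lapply(names(config$species_thresholds), function(sp) {
    code <- substr(sp, 1, 2)
    n <- config$n_plots_per_species
    per_cat <- ceiling(n / length(config$categories))
    cats <- rep(config$categories, each = per_cat)[seq_len(n)]
    data.frame(plot_id = sprintf("%s%02d", code, seq_len(n)),
               species = sp, category = cats)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate daily and monthly climate with injected dry spells
#'
#' Daily temperature follows a sinusoidal annual cycle plus Gaussian
#' noise; monthly temperature is the mean of that month's daily values.
#' Monthly precipitation, downward solar radiation and soil moisture get
#' seasonal cycles with noise. In injected drought years the June-August
#' months receive a solar-radiation excess of at least `sr_anomaly`
#' baseline SDs (the anomaly is added on top of folded, non-negative
#' noise), soil moisture is depressed symmetrically, summer temperature is
#' raised and summer precipitation halved, so the dry spells are visible
#' in every climate variable and in SPEI.
#'
#' @param config a [simulation_config()].
#' @return list with `daily` (year, doy, T), `monthly` (year, month, T, P,
#'   SR, SM) and `latitude`.
#' @export
simulate_climate <- function(config) {
  with_seed(config$seed, {
    yrs <- config$years
    daily <- do.call(rbind, lapply(yrs, function(yr) {
      nd <- if (is_leap(yr)) 366L else 365L
      doy <- seq_len(nd)
      tt <- 7 + 10 * sin(2 * pi * (doy - 105) / 365.25) + stats::rnorm(nd, 0, 2)
      if (yr %in% config$drought_years) {
        jja <- doy >= 152 & doy <= 243
        tt[jja] <- tt[jja] + 1.5
      }
      data.frame(year = yr, doy = doy, T = tt)
    }))
    mo_of_doy <- function(yr, doy) {
      as.integer(strftime(as.Date(doy - 1, origin = paste0(yr, "-01-01")), "%m"))
    }
    daily$month <- mo_of_doy(daily$year, daily$doy)
    agg <- stats::aggregate(T ~ year + month, data = daily, FUN = mean)
    agg <- agg[order(agg$year, agg$month), ]
    m <- agg$month
    n <- nrow(agg)
    sd_P <- 15; sd_SR <- 30e6; sd_SM <- 1.5
    seas_P <- 70 + 20 * sin(2 * pi * (m - 3.5) / 12)
    seas_SR <- (400 + 300 * sin(2 * pi * (m - 3.5) / 12)) * 1e6
    seas_SM <- 25 + 5 * sin(2 * pi * (m - 9.5) / 12)
    eP <- stats::rnorm(n, 0, sd_P)
    eSR <- stats::rnorm(n, 0, sd_SR)
    eSM <- stats::rnorm(n, 0, sd_SM)
    P <- pmax(0, seas_P + eP)
    SR <- pmax(0, seas_SR + eSR)
    SM <- pmax(0.5, seas_SM + eSM)
    jja_ev <- agg$year %in% config$drought_years & m %in% 6:8
    SR[jja_ev] <- seas_SR[jja_ev] + config$sr_anomaly * sd_SR + abs(eSR[jja_ev])
    SM[jja_ev] <- pmax(0.5, seas_SM[jja_ev] - config$sr_anomaly * sd_SM - abs(eSM[jja_ev]))
    P[jja_ev] <- 0.5 * P[jja_ev]
    monthly <- data.frame(year = agg$year, month = m, T = agg$T,
                          P = P, SR = SR, SM = SM)
    daily$month <- NULL
    list(daily = daily, monthly = monthly, latitude = config$latitude)
  })
}

# standardized JJA anomalies of a monthly variable (baseline: all years)
jja_anomaly <- function(monthly, var) {
  s <- seasonal_means(monthly, "JJA", var)
  z <- (s[[var]] - mean(s[[var]], na.rm = TRUE)) / stats::sd(s[[var]], na.rm = TRUE)
  stats::setNames(z, s$year)
}

#' Simulate ring-width series for every tree of every plot
#'
#' Each tree's widths follow a negative-exponential age curve
#' \eqn{w(a) = A e^{-a/\tau} + c} multiplied by a climate modifier
#' (fractional response to the standardized summer solar-radiation and
#' soil-moisture anomalies), by the event-year drop and the lag-1..4
#' legacy reductions, and by mean-one lognormal AR(1) noise, so widths are
#' always strictly positive. Trees get random ages (mean 113 years) so the
#' series start well before the analysis window and carry a real age
#' trend.
#'
#' @param climate output of [simulate_climate()].
#' @param plots data.frame from [simulate_plots()].
#' @param config a [simulation_config()].
#' @param age_curve list with positive `A_range`, `tau_range`, `c_range`
#'   (per-tree parameters drawn uniformly from these ranges).
#' @return named list of [ring_width_series()] objects.
#' @export
simulate_ring_widths <- function(climate, plots, config,
                                 age_curve = list(A_range = c(2, 4),
                                                  tau_range = c(40, 80),
                                                  c_range = c(0.3, 0.8))) {
  if (any(unlist(age_curve) <= 0)) stop("age-curve parameters must be positive")
  if (!all(config$years %in% unique(climate$monthly$year))) {
    stop("climate does not cover the configured years")
  }
  zSR <- jja_anomaly(climate$monthly, "SR")
  zSM <- jja_anomaly(climate$monthly, "SM")
  last_year <- max(config$years)
  eff <- c(config$growth_drop, config$legacy)  # lags 0..4
  with_seed(config$seed + 1L, {
    out <- list()
    for (i in seq_len(nrow(plots))) {
      pid <- plots$plot_id[i]
      for (tr in seq_len(config$trees_per_plot)) {
        age <- round(stats::rnorm(1, 113, 15))
        age <- min(max(age, 70), 160)
        yrs <- (last_year - age + 1):last_year
        a <- seq_along(yrs)
        A <- stats::runif(1, age_curve$A_range[1], age_curve$A_range[2])
        tau <- stats::runif(1, age_curve$tau_range[1], age_curve$tau_range[2])
        cc <- stats::runif(1, age_curve$c_range[1], age_curve$c_range[2])
        w <- A * exp(-a / tau) + cc
        clim <- 1 + config$coupling_sr * ifelse(is.na(zSR[as.character(yrs)]), 0,
                                                zSR[as.character(yrs)]) +
          config$coupling_sm * ifelse(is.na(zSM[as.character(yrs)]), 0,
                                      zSM[as.character(yrs)])
        evmult <- rep(1, length(yrs))
        for (l in 0:4) {
          hit <- yrs %in% (config$drought_years + l)
          evmult[hit] <- evmult[hit] * (1 - eff[l + 1])
        }
        if (config$ring_sd > 0) {
          innov_sd <- config$ring_sd * sqrt(1 - config$ring_ar^2)
          x <- numeric(length(yrs))
          x[1] <- stats::rnorm(1, 0, config$ring_sd)
          for (k in seq_along(yrs)[-1]) {
            x[k] <- config$ring_ar * x[k - 1] + stats::rnorm(1, 0, innov_sd)
          }
          noise <- exp(x - config$ring_sd^2 / 2)
        } else {
          noise <- rep(1, length(yrs))
        }
        widths <- w * pmax(clim, 0.05) * evmult * noise
        tid <- sprintf("%sT%02d", pid, tr)
        out[[tid]] <- ring_width_series(tid, pid, yrs[1], widths)
      }
    }
    out
  })
}

#' Simulate reflectance scene stacks with ground truth
#'
#' For each plot a 2x2 pixel neighbourhood is observed every 8 days
#' through the season. The per-pixel true NDVI is a base level plus a
#' linear year drift, a within-season bell shape, the event-year dip, the
#' lag-1..2 rebound and a fixed small pixel offset; AR(1) Gaussian noise
#' is added per pixel-date, the value clamped to [-1, 1] (clamps are
#' counted), and converted to red/NIR reflectances with a fixed total
#' reflectance of 0.5. Each pixel-date is cloud-masked with probability
#' `cloud_fraction` (masked rows carry NA reflectances). The generator
#' also records, per pixel and year, the growing-season median of the
#' noise-free NDVI - the ground truth the compositing pipeline should
#' recover.
#'
#' @param climate output of [simulate_climate()] (daily T fixes the
#'   growing-season windows).
#' @param plots data.frame from [simulate_plots()].
#' @param config a [simulation_config()].
#' @return list with `scenes` (data.frame: scene_id, date, plot_id,
#'   pixel_id, red, nir, cloud_flag), `weights` (data.frame: plot_id,
#'   pixel_id, weight), `truth` (data.frame: plot_id, pixel_id, year,
#'   true_median), `windows` (plot_id, year, start_doy, end_doy),
#'   `n_clamped`.
#' @export
simulate_scenes <- function(climate, plots, config) {
  doys <- seq(57, 305, by = 8)
  yrs <- config$years
  y0 <- min(yrs)
  base_w <- c(0.4, 0.3, 0.2, 0.1)
  px_off <- c(-0.01, 0, 0.005, 0.01)
  with_seed(config$seed + 2L, {
    scenes <- list(); truth <- list(); windows <- list(); weights <- list()
    n_clamped <- 0L
    for (i in seq_len(nrow(plots))) {
      pid <- plots$plot_id[i]
      thr <- config$species_thresholds[[plots$species[i]]]
      pix <- sprintf("%s_px%d", pid, 1:4)
      weights[[pid]] <- data.frame(plot_id = pid, pixel_id = pix, weight = base_w)
      win <- lapply(yrs, function(yr) growing_season_window(climate$daily, yr, thr))
      windows[[pid]] <- data.frame(plot_id = pid, year = yrs,
                                   start_doy = vapply(win, `[[`, 1L, "start_doy"),
                                   end_doy = vapply(win, `[[`, 1L, "end_doy"))
      ev_effect <- numeric(length(yrs))
      ev_effect[yrs %in% config$drought_years] <- -config$ndvi_drop
      reb <- yrs %in% c(config$drought_years + 1, config$drought_years + 2)
      ev_effect[reb] <- ev_effect[reb] + config$ndvi_rebound
      for (j in 1:4) {
        nt <- length(yrs) * length(doys)
        # noise as one AR(1) stream per pixel across all scene dates
        if (config$ndvi_sd > 0) {
          innov <- config$ndvi_sd * sqrt(1 - config$ndvi_ar^2)
          e <- numeric(nt)
          e[1] <- stats::rnorm(1, 0, config$ndvi_sd)
          for (k in 2:nt) e[k] <- config$ndvi_ar * e[k - 1] + stats::rnorm(1, 0, innov)
        } else e <- numeric(nt)
        cl <- stats::runif(nt) < config$cloud_fraction
        k <- 0L
        for (yi in seq_along(yrs)) {
          yr <- yrs[yi]
          seas <- config$ndvi_seasonal_amp * sin(pi * (doys - 57) / (305 - 57))
          v_true <- config$ndvi_base + config$ndvi_trend * (yr - y0) + seas +
            ev_effect[yi] + px_off[j]
          v_obs <- v_true + e[k + seq_along(doys)]
          clamped <- v_obs < -1 | v_obs > 1
          n_clamped <- n_clamped + sum(clamped)
          v_obs <- pmin(1, pmax(-1, v_obs))
          red <- 0.25 * (1 - v_obs)
          nir <- 0.25 * (1 + v_obs)
          flag <- cl[k + seq_along(doys)]
          red[flag] <- NA; nir[flag] <- NA
          scenes[[length(scenes) + 1L]] <- data.frame(
            scene_id = sprintf("S%d_%03d", yr, doys),
            date = as.Date(doys - 1, origin = paste0(yr, "-01-01")),
            plot_id = pid, pixel_id = pix[j],
            red = red, nir = nir, cloud_flag = flag)
          w <- windows[[pid]][yi, ]
          if (!is.na(w$start_doy)) {
            inwin <- doys >= w$start_doy & doys <= w$end_doy
            tm <- if (any(inwin)) stats::median(v_true[inwin]) else NA_real_
          } else tm <- NA_real_
          truth[[length(truth) + 1L]] <- data.frame(
            plot_id = pid, pixel_id = pix[j], year = yr, true_median = tm)
          k <- k + length(doys)
        }
      }
    }
    list(scenes = do.call(rbind, scenes),
         weights = do.call(rbind, weights),
         truth = do.call(rbind, truth),
         windows = do.call(rbind, windows),
         n_clamped = n_clamped)
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs the three generators in sequence (climate, ring widths, scenes)
#' under sub-seeds derived from the configuration seed.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `plots`, `climate`, `rings`, `scenes`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  plots <- simulate_plots(config)
  climate <- simulate_climate(config)
  rings <- simulate_ring_widths(climate, plots, config)
  scenes <- simulate_scenes(climate, plots, config)
  list(config = config, plots = plots, climate = climate, rings = rings,
       scenes = scenes)
}
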