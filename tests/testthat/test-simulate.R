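small_cfg <- function(...) {
  simulation_config(seed = 5, n_plots_per_species = 2, trees_per_plot = 6, ...)
}

test_that("configuration validation catches bad inputs", {
  expect_error(simulation_config(drought_years = c(1980)), "1980")
  expect_error(simulation_config(drought_years = c(1994, 1995)), "non-consecutive")
  expect_error(simulation_config(growth_drop = 1.2), "fractions")
  expect_error(simulate_ring_widths(simulate_climate(small_cfg()),
                                    simulate_plots(small_cfg()), small_cfg(),
                                    age_curve = list(A_range = c(-1, 1),
                                                     tau_range = c(40, 80),
                                                     c_range = c(0.3, 0.8))),
               "positive")
})

test_that("plot metadata has the configured category structure", {
  p <- simulate_plots(simulation_config())
  expect_equal(nrow(p), 40)
  expect_equal(as.integer(table(p$species)), c(20L, 20L))
  expect_true(all(table(p$category, p$species) == 5))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  c1 <- simulate_climate(cfg)
  c2 <- simulate_climate(cfg)
  expect_identical(c1, c2)
  p <- simulate_plots(cfg)
  r1 <- simulate_ring_widths(c1, p, cfg)
  r2 <- simulate_ring_widths(c1, p, cfg)
  expect_identical(r1, r2)
  s1 <- simulate_scenes(c1, p, cfg)
  s2 <- simulate_scenes(c1, p, cfg)
  expect_identical(s1, s2)
})

test_that("monthly temperature equals the mean of the month's daily values", {
  cl <- simulate_climate(small_cfg())
  d <- cl$daily
  d$month <- as.integer(strftime(as.Date(d$doy - 1,
                                         origin = paste0(d$year, "-01-01")), "%m"))
  for (yr in c(1985, 1994, 2017)) {
    for (m in c(1, 6, 12)) {
      expect_equal(cl$monthly$T[cl$monthly$year == yr & cl$monthly$month == m],
                   mean(d$T[d$year == yr & d$month == m]), tolerance = 1e-10)
    }
  }
})

test_that("injected years carry the configured summer radiation anomaly", {
  cfg <- small_cfg(sr_anomaly = 2)
  cl <- simulate_climate(cfg)
  jja <- seasonal_means(cl$monthly, "JJA", "SR")
  base <- jja$SR[!jja$year %in% cfg$drought_years]
  z <- (jja$SR - mean(base)) / sd(base)
  # recomputed from the output: every injected year at least 2 baseline SDs up
  expect_true(all(z[jja$year %in% cfg$drought_years] >= 2))
  sm <- seasonal_means(cl$monthly, "JJA", "SM")
  expect_true(all(sm$SM[sm$year %in% cfg$drought_years] < mean(sm$SM)))
})

test_that("ring widths are strictly positive with the configured series count", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  expect_length(ds$rings, 4 * 6)
  expect_true(all(sapply(ds$rings, function(s) all(s$widths > 0))))
  expect_true(all(sapply(ds$rings, function(s) length(s$widths) >= 70)))
})

test_that("the age curve is non-increasing when coupling and noise are off", {
  cfg <- small_cfg(ring_sd = 0, coupling_sr = 0, coupling_sm = 0,
                   growth_drop = 0, legacy = rep(0, 4))
  ds <- simulate_dataset(cfg)
  for (s in ds$rings[1:5]) {
    expect_true(all(diff(s$widths) <= 1e-12))
  }
})

test_that("noise-free drop-free generation detrends to a flat index", {
  cfg <- small_cfg(ring_sd = 0, coupling_sr = 0, coupling_sm = 0,
                   growth_drop = 0, legacy = rep(0, 4))
  ds <- simulate_dataset(cfg)
  # a smoothing spline tracks, but does not interpolate, a negative
  # exponential: small residual curvature remains, largest at the ends
  for (s in ds$rings[seq(1, 24, by = 5)]) {
    d <- spline_detrend(s, 30)
    n <- length(d$tri)
    expect_lt(max(abs(d$tri - 1)), 0.01)
    expect_lt(max(abs(d$tri[16:(n - 15)] - 1)), 0.005)
  }
})

test_that("scene NDVI stays in [-1, 1] and reflectances invert to the truth", {
  cfg <- small_cfg(ndvi_sd = 0, cloud_fraction = 0)
  ds <- simulate_dataset(cfg)
  nd <- compute_ndvi(ds$scenes$scenes$nir, ds$scenes$scenes$red)
  expect_true(all(nd >= -1 & nd <= 1, na.rm = TRUE))
  # noise-free: composite + extraction reproduces recorded ground truth exactly
  pid <- ds$plots$plot_id[1]
  thr <- cfg$species_thresholds[[ds$plots$species[1]]]
  sc <- ds$scenes$scenes[ds$scenes$scenes$plot_id == pid, ]
  for (yr in c(1985, 1994, 2000, 2017)) {
    win <- growing_season_window(ds$climate$daily, yr, thr)
    comp <- annual_median_composite(sc, win, yr)
    tr <- ds$scenes$truth
    tr <- tr[tr$plot_id == pid & tr$year == yr, ]
    m <- merge(comp, tr, by = "pixel_id")
    expect_equal(m$ndvi, m$true_median, tolerance = 1e-12)
    w <- ds$scenes$weights[ds$scenes$weights$plot_id == pid, ]
    pv <- extract_plot_value(comp, setNames(w$weight, w$pixel_id))
    expect_equal(pv, sum(w$weight * m$true_median), tolerance = 1e-12)
  }
})

test_that("the cloud mask hits close to the configured fraction", {
  cfg <- small_cfg(cloud_fraction = 0.3)
  ds <- simulate_scenes(simulate_climate(cfg), simulate_plots(cfg), cfg)
  n <- nrow(ds$scenes)
  expect_gte(n, 1000)
  expect_lt(abs(mean(ds$scenes$cloud_flag) - 0.3), 0.05)
  expect_true(all(is.na(ds$scenes$red[ds$scenes$cloud_flag])))
})

test_that("the dataset writers produce a readable interchange bundle", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_rwl(paths$rwl[1])
  ids <- names(back)
  orig <- ds$rings[[ids[1]]]
  expect_equal(back[[1]]$years, orig$years)
  expect_lt(max(abs(back[[1]]$widths - orig$widths)), 0.00501)  # 0.01 mm files
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_equal(sort(gt$drought_years), cfg$drought_years)
})
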