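#' Default pipeline configuration
#'
#' @param seed integer seed (governs the synthetic generators and the SEA
#'   resampling null).
#' @param out_dir output directory.
#' @param mode `"synthetic"` (generate inputs) or `"data"` (read them
#'   from the configured paths).
#' @param simulation a [simulation_config()] (synthetic mode).
#' @param paths named list for data mode: `rwl` (one or more Tucson
#'   files), `scenes`, `daily_climate`, `monthly_climate`, `metadata`,
#'   `weights` (CSV files).
#' @param spline_wavelength spline cutoff in years (default 30).
#' @param min_depth minimum chronology sample depth (default 5).
#' @param spei_scale SPEI accumulation window in months (default 4).
#' @param n_events number of drought years to select (default 4).
#' @param event_variable seasonal variable driving event selection
#'   (default `"SR"`, direction max; `"SM"` uses direction min).
#' @param sea_lag,sea_resamples SEA window half-width and null draws.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("dryspell_run_"),
                            mode = c("synthetic", "data"),
                            simulation = simulation_config(seed = seed),
                            paths = list(),
                            spline_wavelength = 30, min_depth = 5,
                            spei_scale = 4, n_events = 4,
                            event_variable = c("SR", "SM"),
                            sea_lag = 4, sea_resamples = 1000) {
  mode <- match.arg(mode)
  event_variable <- match.arg(event_variable)
  stopifnot(spline_wavelength > 0, min_depth > 0, spei_scale > 0,
            n_events > 0, sea_lag > 0, sea_resamples > 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir, mode = mode,
                 simulation = simulation, paths = paths,
                 spline_wavelength = spline_wavelength, min_depth = min_depth,
                 spei_scale = spei_scale, n_events = n_events,
                 event_variable = event_variable, sea_lag = sea_lag,
                 sea_resamples = sea_resamples),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` block mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @param overrides named list of values overriding file keys (e.g. from
#'   the command line).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  sim_args <- y$simulation
  y$simulation <- NULL
  if (!is.null(y$seed) && is.null(sim_args$seed)) sim_args$seed <- y$seed
  args <- y
  args$simulation <- do.call(simulation_config, as.list(sim_args))
  do.call(pipeline_config, args)
}

#' Run the full dry-spell analysis pipeline
#'
#' Executes every stage in order: input acquisition (synthetic generation
#' or CSV/RWL reading), ring-width detrending and plot chronologies,
#' growing-season NDVI compositing and linear detrending, PET/SPEI and
#' seasonal climate aggregation, severity anomalies and non-consecutive
#' drought-year selection, superposed epoch analysis of every plot series,
#' climate correlations, mixed-model fitting of the three severity
#' variants per species and response, and Lloret resilience metrics.
#' Writes tidy CSV tables plus a machine-readable JSON manifest to
#' `config$out_dir` and returns the results invisibly. Deterministic for
#' a fixed seed.
#'
#' @param config a [pipeline_config()] or the path to a YAML file.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message("[dryspell] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  # --- inputs -------------------------------------------------------------
  if (config$mode == "synthetic") {
    say("generating synthetic dataset (seed ", config$seed, ")")
    ds <- simulate_dataset(config$simulation)
  } else {
    ds <- read_input_bundle(config)
  }
  plots <- ds$plots
  analysis_years <- sort(unique(ds$climate$monthly$year))

  # --- tree rings ---------------------------------------------------------
  say("detrending ", length(ds$rings), " ring-width series")
  chron <- list()
  dropped_series <- 0L
  for (pid in plots$plot_id) {
    det <- list()
    for (s in ds$rings) {
      if (!identical(s$plot_id, pid)) next
      d <- tryCatch(spline_detrend(s, config$spline_wavelength),
                    error = function(e) NULL)
      if (is.null(d)) dropped_series <- dropped_series + 1L else det[[s$tree_id]] <- d
    }
    if (length(det) == 0) next
    ch <- build_chronology(det, pid, min_depth = config$min_depth)
    keep <- ch$years %in% analysis_years
    ch$years <- ch$years[keep]; ch$index <- ch$index[keep]
    ch$sample_depth <- ch$sample_depth[keep]
    chron[[pid]] <- ch
  }
  chron_tab <- chronology_table(chron)

  # --- greenness ----------------------------------------------------------
  say("compositing NDVI scenes")
  scn <- ds$scenes$scenes
  scn$.year <- as.integer(strftime(scn$date, "%Y"))
  scn$.doy <- as.integer(strftime(scn$date, "%j"))
  green <- list(); window_rows <- list()
  for (pid in plots$plot_id) {
    thr <- config$simulation$species_thresholds[[plots$species[match(pid, plots$plot_id)]]]
    sp_sc <- scn[scn$plot_id == pid, ]
    wrow <- ds$scenes$weights[ds$scenes$weights$plot_id == pid, ]
    w <- stats::setNames(wrow$weight, wrow$pixel_id)
    nd <- rep(NA_real_, length(analysis_years))
    for (yi in seq_along(analysis_years)) {
      yr <- analysis_years[yi]
      win <- growing_season_window(ds$climate$daily, yr, thr)
      window_rows[[length(window_rows) + 1L]] <- data.frame(
        plot_id = pid, year = yr, start_doy = win$start_doy,
        end_doy = win$end_doy, empty = win$empty)
      if (win$empty) next
      comp <- annual_median_composite(sp_sc[sp_sc$.year == yr, ], win, yr)
      nd[yi] <- extract_plot_value(comp, w)
    }
    green[[pid]] <- detrend_linear_residuals(analysis_years, nd, plot_id = pid)
  }
  green_tab <- do.call(rbind, lapply(green, function(g) {
    data.frame(plot_id = g$plot_id, year = g$years, ndvi = g$ndvi,
               residual = g$residual, row.names = NULL)
  }))

  # --- climate indices ----------------------------------------------------
  say("computing PET, SPEI and seasonal series")
  mon <- thornthwaite_pet(ds$climate$monthly, ds$climate$latitude)
  mon <- spei(mon, scale = config$spei_scale, calibration = analysis_years)
  seasonal <- list()
  for (season in c("JJA", "GS")) {
    seasonal[[season]] <- seasonal_means(mon, season)
  }
  seas_tab <- do.call(rbind, lapply(names(seasonal), function(tag) {
    s <- seasonal[[tag]]
    stats::reshape(s, direction = "long",
                   varying = setdiff(names(s), c("year", "season")),
                   v.names = "value", timevar = "variable",
                   times = setdiff(names(s), c("year", "season")))[,
      c("year", "season", "variable", "value")]
  }))
  rownames(seas_tab) <- NULL

  sev <- severity_anomalies(seasonal$JJA, config$event_variable,
                            baseline = analysis_years)
  events <- select_drought_years(sev, n = config$n_events,
                                 direction = if (config$event_variable == "SR") "max" else "min",
                                 site = "site", variable = config$event_variable)
  say("selected drought years: ", paste(events$years, collapse = ", "))

  # --- superposed epoch analysis ------------------------------------------
  say("superposed epoch analysis (", config$sea_resamples, " resamples)")
  sea_rows <- list()
  dropped_events <- 0L
  for (pid in names(chron)) {
    ch <- chron[[pid]]
    r <- withCallingHandlers(
      superposed_epoch(ch$years, ch$index, events, lag = config$sea_lag,
                       resamples = config$sea_resamples,
                       seed = config$seed + 10L, series_id = paste0("TRI_", pid)),
      warning = function(w) {
        dropped_events <<- dropped_events + 1L
        invokeRestart("muffleWarning")
      })
    sea_rows[[length(sea_rows) + 1L]] <-
      cbind(series_id = r$series_id, r$table)
  }
  for (pid in names(green)) {
    g <- green[[pid]]
    if (sum(!is.na(g$residual)) < 2 * config$sea_lag + 1) next
    r <- withCallingHandlers(
      superposed_epoch(g$years, g$residual, events, lag = config$sea_lag,
                       resamples = config$sea_resamples,
                       seed = config$seed + 11L, series_id = paste0("NDVI_", pid)),
      warning = function(w) {
        dropped_events <<- dropped_events + 1L
        invokeRestart("muffleWarning")
      })
    sea_rows[[length(sea_rows) + 1L]] <-
      cbind(series_id = r$series_id, r$table)
  }
  sea_tab <- do.call(rbind, sea_rows)

  # --- climate-growth correlations ----------------------------------------
  say("climate correlations")
  clim_list <- list()
  for (tag in names(seasonal)) {
    for (v in c("T", "P", "SR", "SM", "SPEI")) {
      if (v %in% names(seasonal[[tag]])) {
        clim_list[[paste(v, tag, sep = "_")]] <-
          seasonal[[tag]][, c("year", v)]
      }
    }
  }
  corr_rows <- list()
  for (sp in unique(plots$species)) {
    pids <- plots$plot_id[plots$species == sp]
    ch_mat <- sapply(chron[intersect(pids, names(chron))],
                     function(ch) ch$index[match(analysis_years, ch$years)])
    tri_mean <- rowMeans(ch_mat, na.rm = TRUE)
    nd_mat <- sapply(green[intersect(pids, names(green))],
                     function(g) g$residual[match(analysis_years, g$years)])
    ndvi_mean <- rowMeans(nd_mat, na.rm = TRUE)
    corr_rows[[length(corr_rows) + 1L]] <- climate_growth_correlations(
      analysis_years, tri_mean, clim_list, response_id = paste0("TRI_", sp))
    corr_rows[[length(corr_rows) + 1L]] <- climate_growth_correlations(
      analysis_years, ndvi_mean, clim_list, response_id = paste0("NDVI_", sp))
  }
  corr_tab <- do.call(rbind, corr_rows)

  # --- mixed models -------------------------------------------------------
  say("fitting severity mixed models")
  model_rows <- list(); resp_tables <- list(); model_fits <- list()
  for (sp in unique(plots$species)) {
    pids <- plots$plot_id[plots$species == sp]
    tri_series <- lapply(chron[intersect(pids, names(chron))], function(ch) {
      list(years = ch$years, values = ch$index)
    })
    nd_series <- lapply(green[intersect(pids, names(green))], function(g) {
      list(years = g$years, values = g$residual)
    })
    for (resp in c("TRI", "NDVI")) {
      series <- if (resp == "TRI") tri_series else nd_series
      tb <- build_response_table(series, events, sev, plots, response = resp)
      key <- paste(sp, resp, sep = "_")
      resp_tables[[key]] <- tb
      fm <- fit_response_models(tb)
      model_fits[[key]] <- fm$fits
      model_rows[[key]] <- cbind(species = sp, response = resp, fm$summary)
    }
  }
  model_tab <- do.call(rbind, model_rows)
  rownames(model_tab) <- NULL

  # --- resilience ---------------------------------------------------------
  say("resilience metrics")
  resil_rows <- list()
  for (pid in names(chron)) {
    ch <- chron[[pid]]
    for (e in events$years) {
      rm <- tryCatch(
        resilience_metrics(ch$years, ch$index, e,
                           exclude_years = setdiff(events$years, e),
                           plot_id = pid),
        error = function(err) NULL)
      if (is.null(rm)) next
      resil_rows[[length(resil_rows) + 1L]] <- data.frame(
        plot_id = pid, event_year = e, resistance = rm$resistance,
        recovery = rm$recovery, resilience = rm$resilience)
    }
  }
  resil_tab <- do.call(rbind, resil_rows)

  # --- outputs ------------------------------------------------------------
  say("writing outputs to ", config$out_dir)
  outf <- function(name) file.path(config$out_dir, name)
  utils::write.csv(chron_tab, outf("chronologies.csv"), row.names = FALSE)
  utils::write.csv(green_tab, outf("greenness.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, window_rows), outf("season_windows.csv"),
                   row.names = FALSE)
  utils::write.csv(mon, outf("monthly_climate_indices.csv"), row.names = FALSE)
  utils::write.csv(seas_tab, outf("seasonal_climate.csv"), row.names = FALSE)
  utils::write.csv(sea_tab, outf("sea.csv"), row.names = FALSE)
  utils::write.csv(corr_tab, outf("correlations.csv"), row.names = FALSE)
  utils::write.csv(model_tab, outf("models.csv"), row.names = FALSE)
  utils::write.csv(resil_tab, outf("resilience.csv"), row.names = FALSE)
  for (key in names(resp_tables)) {
    utils::write.csv(resp_tables[[key]],
                     outf(paste0("response_table_", key, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(site = events$site, variable = events$variable,
                            years = events$years, severity = events$severity),
                       outf("events.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "dryspell",
    version = as.character(utils::packageVersion("dryspell")),
    seed = config$seed, mode = config$mode,
    parameters = config[c("spline_wavelength", "min_depth", "spei_scale",
                          "n_events", "event_variable", "sea_lag",
                          "sea_resamples")],
    drought_years = events$years,
    n_series = length(ds$rings), n_series_dropped = dropped_series,
    n_sea_truncated_events = dropped_events,
    n_scene_rows = nrow(scn),
    n_clamped_reflectances = if (!is.null(ds$scenes$n_clamped)) ds$scenes$n_clamped else 0,
    tables = list(chronologies = nrow(chron_tab), greenness = nrow(green_tab),
                  sea = nrow(sea_tab), models = nrow(model_tab),
                  resilience = nrow(resil_tab)))
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  invisible(list(config = config, data = ds, chronologies = chron,
                 greenness = green, monthly = mon, seasonal = seasonal,
                 severity = sev, events = events, sea = sea_tab,
                 correlations = corr_tab, response_tables = resp_tables,
                 models = model_tab, model_fits = model_fits,
                 resilience = resil_tab))
}

# Data-mode input reading: CSV tables in the layout the synthetic writers
# produce. Errors name the missing field.
read_input_bundle <- function(config) {
  need <- c("rwl", "scenes", "daily_climate", "monthly_climate", "metadata",
            "weights")
  for (f in need) {
    if (is.null(config$paths[[f]])) {
      stop("data mode: config is missing the input path '", f, "'")
    }
  }
  plots <- utils::read.csv(config$paths$metadata)
  rings <- list()
  pid_map <- NULL
  for (p in config$paths$rwl) {
    rr <- read_rwl(p)
    rings <- c(rings, rr)
  }
  # attach plot ids by longest-prefix match against the metadata
  for (i in seq_along(rings)) {
    hit <- plots$plot_id[startsWith(rings[[i]]$tree_id, plots$plot_id)]
    if (length(hit) >= 1) rings[[i]]$plot_id <- hit[1]
  }
  scenes <- utils::read.csv(config$paths$scenes)
  scenes$date <- as.Date(scenes$date)
  scenes$cloud_flag <- as.logical(scenes$cloud_flag)
  weights <- utils::read.csv(config$paths$weights)
  daily <- utils::read.csv(config$paths$daily_climate)
  monthly <- utils::read.csv(config$paths$monthly_climate)
  lat <- if (!is.null(config$paths$latitude)) config$paths$latitude else
    config$simulation$latitude
  list(config = config$simulation, plots = plots,
       climate = list(daily = daily, monthly = monthly, latitude = lat),
       rings = rings,
       scenes = list(scenes = scenes, weights = weights, truth = NULL,
                     windows = NULL, n_clamped = NULL))
}

#' Write the synthetic dataset to disk in interchange formats
#'
#' RWL per plot, CSV climate/scene/metadata/weight tables and a JSON
#' ground-truth sidecar - the same layout [run_pipeline()] reads in data
#' mode.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory.
#' @return (invisibly) named list of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "rwl"), showWarnings = FALSE)
  paths <- list(rwl = character(0))
  for (pid in unique(dataset$plots$plot_id)) {
    series <- Filter(function(s) identical(s$plot_id, pid), dataset$rings)
    p <- file.path(dir, "rwl", paste0(pid, ".rwl"))
    write_rwl(series, p)
    paths$rwl <- c(paths$rwl, p)
  }
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  paths$daily_climate <- wr(dataset$climate$daily, "daily_climate.csv")
  paths$monthly_climate <- wr(dataset$climate$monthly, "monthly_climate.csv")
  paths$scenes <- wr(dataset$scenes$scenes, "scenes.csv")
  paths$weights <- wr(dataset$scenes$weights, "weights.csv")
  paths$metadata <- wr(dataset$plots, "plot_metadata.csv")
  jsonlite::write_json(list(truth = dataset$scenes$truth,
                            windows = dataset$scenes$windows,
                            drought_years = dataset$config$drought_years),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  invisible(paths)
}
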