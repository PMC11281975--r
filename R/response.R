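#' Build the drought-response table for mixed modelling
#'
#' One row per plot x event x lag (lags 0..4): the response (chronology
#' index, or per-plot standardized NDVI residual), the event-year severity
#' SEV0, and the row-year severity SEV. SEV0 is constant within an event;
#' at lag 0 SEV equals SEV0 by the row-year convention (an alternative
#' setting SEV to 0 at lag 0 is available). Rows whose lag year falls
#' outside the series support are omitted.
#'
#' @param series named list of per-plot annual series: each element a list
#'   with `years` and `values`.
#' @param events event years (integer vector or `"event_set"`).
#' @param severity data.frame with `year`, `severity` (e.g. standardized
#'   JJA solar-radiation anomalies from [severity_anomalies()]).
#' @param metadata data.frame with `plot_id`, `species`, `category`.
#' @param response `"TRI"` or `"NDVI"`; NDVI responses are standardized
#'   per plot (mean 0, SD 1 over the plot's non-missing years).
#' @param max_lag maximum post-event lag (default 4).
#' @param sev_lag0 `"sev0"` (default: SEV = SEV0 at lag 0) or `"zero"`.
#' @return data.frame with columns `species`, `plot_id`, `category`,
#'   `event_year`, `lag`, `response`, `sev0`, `sev`.
#' @export
build_response_table <- function(series, events, severity, metadata,
                                 response = c("TRI", "NDVI"), max_lag = 4,
                                 sev_lag0 = c("sev0", "zero")) {
  response <- match.arg(response)
  sev_lag0 <- match.arg(sev_lag0)
  ev <- if (inherits(events, "event_set")) events$years else as.integer(events)
  sev_of <- function(yr) severity$severity[match(yr, severity$year)]
  if (anyNA(sev_of(ev))) stop("severity anomalies missing for some event year")
  rows <- list()
  for (pid in names(series)) {
    s <- series[[pid]]
    vals <- s$values
    if (response == "NDVI") {
      mu <- mean(vals, na.rm = TRUE)
      sdv <- stats::sd(vals, na.rm = TRUE)
      if (is.na(sdv) || sdv == 0) next
      vals <- (vals - mu) / sdv
    }
    meta <- metadata[match(pid, metadata$plot_id), ]
    for (e in ev) {
      for (l in 0:max_lag) {
        i <- match(e + l, s$years)
        if (is.na(i) || is.na(vals[i])) next
        sv <- if (l == 0 && sev_lag0 == "zero") 0 else sev_of(e + l)
        if (is.na(sv)) next
        rows[[length(rows) + 1L]] <- data.frame(
          species = meta$species, plot_id = pid, category = meta$category,
          event_year = e, lag = l, response = vals[i],
          sev0 = sev_of(e), sev = sv)
      }
    }
  }
  if (length(rows) == 0) stop("no response rows could be built")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the three severity model variants
#'
#' Fits the full model `response ~ sev0 + sev`, and the two reduced
#' variants omitting SEV0 and SEV respectively, each as a random-intercept
#' mixed model with plot category as the grouping factor, and collects the
#' comparison metrics (AIC, marginal/conditional/pseudo R2, predictor
#' t-values, VIF, random-effect LRT p).
#'
#' @param table a [build_response_table()] data.frame.
#' @param group grouping column (default `"category"`).
#' @return list with `fits` (named list of [lmm_ri()] objects) and
#'   `summary` (one row per variant).
#' @export
fit_response_models <- function(table, group = "category") {
  variants <- list(full = response ~ sev0 + sev,
                   without_SEV0 = response ~ sev,
                   without_SEV = response ~ sev0)
  fits <- lapply(variants, lmm_ri, data = table, group = group)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    m <- model_metrics(f)
    lrt <- random_effect_lrt(f)
    vifs <- if (length(f$coefficients) > 2) vif(f) else NULL
    data.frame(variant = nm, AIC = f$AIC,
               r2_marginal = m$r2_marginal, r2_conditional = m$r2_conditional,
               pseudo_r2 = m$pseudo_r2,
               t_sev0 = if ("sev0" %in% names(f$tvalues)) f$tvalues[["sev0"]] else NA,
               t_sev = if ("sev" %in% names(f$tvalues)) f$tvalues[["sev"]] else NA,
               max_vif = if (is.null(vifs)) NA else max(vifs),
               ranef_p = lrt$p, qq_correlation = m$qq_correlation,
               singular = f$singular)
  })
  list(fits = fits, summary = do.call(rbind, rows))
}

#' Lloret-type resilience metrics around a drought event
#'
#' resistance = event value / pre-window mean; recovery = post-window mean
#' / event value; resilience = post-window mean / pre-window mean (so that
#' resilience = resistance x recovery exactly). Windows default to the 3
#' years before and after the event; other event years can be excluded
#' from the windows.
#'
#' @param years,values the annual performance series (e.g. chronology).
#' @param event_year the drought year.
#' @param pre_years,post_years window lengths (default 3).
#' @param exclude_years years to drop from the windows (e.g. other events).
#' @param plot_id label.
#' @return object of class `"resilience_metrics"`: list with `plot_id`,
#'   `event_year`, `resistance`, `recovery`, `resilience`, `pre_mean`,
#'   `post_mean`, `event_value`, `pre_years`, `post_years`.
#' @export
resilience_metrics <- function(years, values, event_year, pre_years = 3,
                               post_years = 3, exclude_years = integer(0),
                               plot_id = "plot") {
  i <- match(event_year, years)
  if (is.na(i)) stop("event year ", event_year, " not in series")
  pre_w <- setdiff(seq(event_year - pre_years, event_year - 1), exclude_years)
  post_w <- setdiff(seq(event_year + 1, event_year + post_years), exclude_years)
  if (!all(pre_w %in% years) || !all(post_w %in% years)) {
    stop("pre/post window extends beyond the series support")
  }
  ev <- values[i]
  pre <- mean(values[match(pre_w, years)], na.rm = TRUE)
  post <- mean(values[match(post_w, years)], na.rm = TRUE)
  if (is.na(ev) || ev == 0) stop("event value is missing or zero")
  if (is.na(pre) || pre == 0) stop("pre-window mean is missing or zero")
  structure(list(plot_id = plot_id, event_year = event_year,
                 resistance = ev / pre, recovery = post / ev,
                 resilience = post / pre,
                 pre_mean = pre, post_mean = post, event_value = ev,
                 pre_years = pre_years, post_years = post_years),
            class = "resilience_metrics")
}

#' @export
print.resilience_metrics <- function(x, ...) {
  cat("Resilience metrics", x$plot_id, "event", x$event_year, ":",
      "Rt =", round(x$resistance, 3), "Rc =", round(x$recovery, 3),
      "Rs =", round(x$resilience, 3), "\n")
  invisible(x)
}
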