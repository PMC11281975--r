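#' Superposed epoch analysis
#'
#' Measures the mean departure of an annual series at fixed lags around
#' event years and attaches an empirical two-sided significance from a
#' resampling null. The departure at lag l is the mean of the series over
#' event years shifted by l, minus the overall series mean. The null is
#' built by drawing `resamples` random event sets of the same size,
#' uniformly without replacement from the years whose full lag window lies
#' inside the series; by default the draws preserve the non-consecutiveness
#' of real drought-year sets.
#'
#' Events whose window would be truncated by the series edge are dropped
#' with a warning; if all events are dropped an error is raised.
#'
#' @param years calendar years of the series (contiguous).
#' @param values annual values (chronology index or NDVI residual).
#' @param events an [select_drought_years()] event set, or integer years.
#' @param lag maximum lag (default 4; lags -lag .. +lag are reported).
#' @param resamples number of null draws (default 1000).
#' @param seed integer seed for the null draws.
#' @param nonconsecutive_null constrain null event sets to be
#'   non-consecutive like the real ones (default TRUE).
#' @param series_id label stored in the result.
#' @return object of class `"sea_result"`: data.frame `table` with `lag`,
#'   `departure`, `p`, plus `n_events`, `resamples`, `seed`, `series_id`.
#' @export
superposed_epoch <- function(years, values, events, lag = 4, resamples = 1000,
                             seed = 1, nonconsecutive_null = TRUE,
                             series_id = "series") {
  ev <- if (inherits(events, "event_set")) events$years else as.integer(events)
  stopifnot(length(years) == length(values), all(diff(years) == 1))
  ok_ev <- ev - lag >= min(years) & ev + lag <= max(years) &
    ev %in% years[!is.na(values)]
  if (any(!ok_ev)) {
    warning("dropping ", sum(!ok_ev), " event(s) with truncated lag window: ",
            paste(ev[!ok_ev], collapse = ", "))
    ev <- ev[ok_ev]
  }
  if (length(ev) == 0) stop("no event with a complete lag window remains")
  mu <- mean(values, na.rm = TRUE)
  lags <- -lag:lag
  pos <- match(ev, years)
  dep <- vapply(lags, function(l) mean(values[pos + l]) - mu, numeric(1))

  # candidate years for the null: full window inside the series
  cand <- which(years - lag >= min(years) & years + lag <= max(years) &
                  !is.na(values))
  nev <- length(ev)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  null_dep <- matrix(NA_real_, resamples, length(lags))
  for (r in seq_len(resamples)) {
    repeat {
      s <- sort(sample(cand, nev))
      if (!nonconsecutive_null || nev == 1 || all(diff(s) > 1)) break
    }
    for (j in seq_along(lags)) {
      null_dep[r, j] <- mean(values[s + lags[j]]) - mu
    }
  }
  p <- vapply(seq_along(lags), function(j) {
    (1 + sum(abs(null_dep[, j]) >= abs(dep[j]))) / (resamples + 1)
  }, numeric(1))
  structure(list(table = data.frame(lag = lags, departure = dep, p = p),
                 n_events = nev, resamples = resamples, seed = seed,
                 series_id = series_id),
            class = "sea_result")
}

#' @export
print.sea_result <- function(x, ...) {
  cat("Superposed epoch analysis:", x$series_id, "(", x$n_events, "events,",
      x$resamples, "resamples )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pearson climate-growth/greenness correlations
#'
#' Correlates an annual response series (TRI chronology or NDVI residuals)
#' with seasonal climate series in the current year and, via a one-year
#' offset, the previous year. Two-sided p-values come from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param resp_years,resp_values the response series.
#' @param climate_seasonal named list of data.frames (one per
#'   variable-season combination) each with `year` and a value column
#'   (last column used).
#' @param offsets year offsets; 0 = current year, -1 = previous year.
#' @param response_id label.
#' @return data.frame with `response`, `climate`, `offset`, `r`, `p`, `n`;
#'   zero-variance pairs yield NA with `degenerate = TRUE`.
#' @export
climate_growth_correlations <- function(resp_years, resp_values,
                                        climate_seasonal, offsets = c(0, -1),
                                        response_id = "response") {
  rows <- list()
  for (nm in names(climate_seasonal)) {
    cs <- climate_seasonal[[nm]]
    cy <- cs$year
    cv <- cs[[ncol(cs)]]
    for (off in offsets) {
      # climate year + |off| aligns previous-year climate with the response
      m <- match(resp_years + off, cy)
      ok <- !is.na(m) & !is.na(resp_values) & !is.na(cv[m])
      n <- sum(ok)
      if (n < 3) next
      x <- resp_values[ok]
      y <- cv[m[ok]]
      degen <- stats::sd(x) == 0 || stats::sd(y) == 0
      if (degen) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(x, y)
        tv <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tv), df = n - 2)
        if (abs(r) == 1) p <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        response = response_id, climate = nm, offset = off,
        r = r, p = p, n = n, degenerate = degen)
    }
  }
  do.call(rbind, rows)
}
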