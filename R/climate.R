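#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite PET from monthly mean temperature with day-length
#' and month-length correction. The annual heat index is
#' \eqn{I = \sum_m (T_m/5)^{1.514}} over months with \eqn{T_m > 0}; the
#' exponent is \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.792\times10^{-2} I + 0.49239}; uncorrected PET is
#' \eqn{16 (10 T/I)^a} mm per standard month (30 days, 12 h of daylight),
#' with the usual hot-month polynomial above 26.5 degC, then multiplied by
#' \eqn{(N/12)(d/30)} where N is the mean day length (h) and d the number
#' of days in the month. PET is 0 for months at or below freezing.
#'
#' @param climate data.frame with columns `year`, `month`, `T` (degC).
#' @param latitude site latitude in degrees (-90..90), used for day length.
#' @return the input data.frame with a `PET` column (mm/month) appended.
#' @export
thornthwaite_pet <- function(climate, latitude) {
  stopifnot(all(c("year", "month", "T") %in% names(climate)))
  if (latitude < -90 || latitude > 90) {
    stop("latitude must be in [-90, 90], got ", latitude)
  }
  if (length(unique(climate$month)) < 12) {
    stop("all 12 calendar months are needed for the annual heat index")
  }
  # heat index per year from that year's monthly means
  pet <- numeric(nrow(climate))
  for (yr in unique(climate$year)) {
    sel <- climate$year == yr
    Tm <- climate$T[sel]
    mo <- climate$month[sel]
    I <- sum((pmax(Tm, 0) / 5)^1.514)
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    pe <- numeric(length(Tm))
    warm <- Tm > 0 & Tm < 26.5
    hot <- Tm >= 26.5
    if (I > 0) pe[warm] <- 16 * (10 * Tm[warm] / I)^a
    pe[hot] <- -415.85 + 32.24 * Tm[hot] - 0.43 * Tm[hot]^2
    K <- month_daylength_hours(mo, latitude) / 12 * days_in_month(yr, mo) / 30
    pet[sel] <- pe * K
  }
  climate$PET <- pet
  climate
}

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- dm[month]
  d[month == 2 & is_leap(year)] <- 29
  d
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

# mean day length (hours) at the mid-month day of year
month_daylength_hours <- function(month, latitude) {
  mid_doy <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  J <- mid_doy[month]
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  phi <- latitude * pi / 180
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))
  24 / pi * ws
}

#' Standardised precipitation-evapotranspiration index (SPEI)
#'
#' Computes the climatic water balance D = P - PET, accumulates it over a
#' window of `scale` months ending in (and including) each month, fits a
#' three-parameter log-logistic distribution to each calendar month's
#' accumulated values over the calibration period using unbiased
#' probability-weighted moments, and transforms the fitted cumulative
#' probabilities to standard-normal quantiles.
#'
#' @param climate data.frame with columns `year`, `month`, `P` and `PET`
#'   (mm), contiguous monthly coverage.
#' @param scale accumulation window in months (default 4).
#' @param calibration integer vector of calibration years (default: all
#'   years present).
#' @return the input data.frame with columns `D_acc` (accumulated balance,
#'   NA for the first `scale - 1` months) and `SPEI` appended.
#' @export
spei <- function(climate, scale = 4, calibration = NULL) {
  stopifnot(all(c("year", "month", "P", "PET") %in% names(climate)))
  ord <- order(climate$year, climate$month)
  climate <- climate[ord, ]
  if (is.null(calibration)) calibration <- unique(climate$year)
  d <- climate$P - climate$PET
  n <- length(d)
  acc <- rep(NA_real_, n)
  if (n >= scale) {
    cs <- cumsum(d)
    acc[scale:n] <- cs[scale:n] - c(0, cs)[(scale:n) - scale + 1]
  }
  z <- rep(NA_real_, n)
  for (m in 1:12) {
    sel <- which(climate$month == m & !is.na(acc))
    cal <- sel[climate$year[sel] %in% calibration]
    if (length(cal) < 20) {
      stop("calendar month ", m, ": fewer than 20 calibration values after accumulation")
    }
    xc <- acc[cal]
    if (stats::sd(xc) == 0) {
      stop("degenerate (constant) accumulated series for calendar month ", m)
    }
    par <- loglogistic_pwm(xc)
    p <- loglogistic_cdf(acc[sel], par)
    z[sel] <- stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6))
  }
  climate$D_acc <- acc
  climate$SPEI <- z
  climate
}

# three-parameter log-logistic fit by unbiased probability-weighted moments
loglogistic_pwm <- function(x) {
  n <- length(x)
  xs <- sort(x)
  i <- seq_len(n)
  b0 <- mean(xs)
  b1 <- sum((i - 1) / (n - 1) * xs) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * xs) / n
  # unbiased PWMs w_s = E[X (1-F)^s]: w0 = b0, w1 = b0 - b1, w2 = b0 - 2 b1 + b2
  w0 <- b0
  w1 <- b0 - b1
  w2 <- b0 - 2 * b1 + b2
  beta <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  # negative shape = reflected (upper-bounded) log-logistic, valid for
  # left-skewed water balances; the mean exists for |beta| > 1
  if (!is.finite(beta) || abs(beta) <= 1) {
    stop("log-logistic PWM fit failed: shape parameter ", round(beta, 3),
         " outside the valid range")
  }
  g <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w0 - 2 * w1) * beta / g
  gam <- w0 - alpha * g
  list(alpha = alpha, beta = beta, gamma = gam)
}

loglogistic_cdf <- function(x, par) {
  z <- (x - par$gamma) / par$alpha
  # support is z > 0; below/above the bound the CDF saturates at 0 or 1
  # depending on whether gamma is a lower (alpha > 0) or upper bound
  ifelse(z <= 0, ifelse(par$alpha > 0, 0, 1), 1 / (1 + z^(-par$beta)))
}

#' Seasonal means of a monthly climate series
#'
#' @param climate data.frame with `year`, `month` and the variable columns.
#' @param season `"JJA"` (June-August) or `"GS"` (May-September), or an
#'   integer vector of months.
#' @param variables character vector of column names to average.
#' @return data.frame with `year`, `season` and one mean per variable;
#'   years missing any season month get NA.
#' @export
seasonal_means <- function(climate, season = c("JJA", "GS"),
                           variables = intersect(c("T", "P", "SR", "SM", "SPEI"),
                                                 names(climate))) {
  if (is.character(season)) {
    tag <- match.arg(season)
    months <- if (tag == "JJA") 6:8 else 5:9
  } else {
    months <- as.integer(season)
    tag <- paste(months, collapse = "-")
  }
  yrs <- sort(unique(climate$year))
  out <- data.frame(year = yrs, season = tag)
  for (v in variables) {
    out[[v]] <- vapply(yrs, function(yr) {
      sel <- climate$year == yr & climate$month %in% months
      vals <- climate[[v]][sel]
      if (sum(sel) < length(months) || anyNA(vals)) return(NA_real_)
      mean(vals)
    }, numeric(1))
  }
  out
}

#' Severity anomalies of a seasonal series
#'
#' Deviation of each year's value from the baseline-period mean,
#' standardized by the baseline standard deviation by default (so that,
#' e.g., solar-radiation severities in J/m2 become unitless and model
#' coefficients comparable across variables).
#'
#' @param seasonal data.frame with `year` and a value column.
#' @param variable name of the value column.
#' @param baseline integer years of the baseline period (default: all).
#' @param standardize divide by the baseline SD (default TRUE).
#' @return data.frame with `year` and `severity`.
#' @export
severity_anomalies <- function(seasonal, variable, baseline = NULL,
                               standardize = TRUE) {
  x <- seasonal[[variable]]
  if (is.null(baseline)) baseline <- seasonal$year
  base <- x[seasonal$year %in% baseline]
  base <- base[!is.na(base)]
  if (length(base) < 5) stop("baseline must span at least 5 years with data")
  anom <- x - mean(base)
  if (standardize) anom <- anom / stats::sd(base)
  data.frame(year = seasonal$year, severity = anom)
}

#' Select the most severe non-consecutive drought years
#'
#' Greedy extreme-first selection: repeatedly take the most extreme
#' remaining year (highest severity for `direction = "max"`, lowest for
#' `"min"`) whose immediate neighbours (+/- 1 year) have not already been
#' selected, until `n` years are chosen. Ties break toward the earlier
#' year. Non-consecutive selection avoids compounding the effects of
#' back-to-back drought years.
#'
#' @param severity data.frame with `year` and `severity`.
#' @param n number of event years (default 4).
#' @param direction `"max"` (e.g. solar radiation) or `"min"` (e.g. soil
#'   moisture).
#' @param site,variable labels stored in the result.
#' @return an object of class `"event_set"`: list with `site`, `variable`,
#'   `years` (ordered), `severity` (at those years).
#' @export
select_drought_years <- function(severity, n = 4, direction = c("max", "min"),
                                 site = "site", variable = "SR") {
  direction <- match.arg(direction)
  ok <- !is.na(severity$severity)
  yrs <- severity$year[ok]
  sev <- severity$severity[ok]
  if (direction == "min") sev <- -sev
  chosen <- integer(0)
  avail <- rep(TRUE, length(yrs))
  while (length(chosen) < n) {
    cand <- which(avail)
    if (length(cand) == 0) stop("cannot select ", n, " non-consecutive years")
    best <- cand[order(-sev[cand], yrs[cand])][1]
    chosen <- c(chosen, best)
    avail[best] <- FALSE
    avail[abs(yrs - yrs[best]) <= 1] <- FALSE
  }
  ord <- order(yrs[chosen])
  ev <- yrs[chosen][ord]
  stopifnot(all(diff(ev) > 1))
  structure(list(site = site, variable = variable, years = ev,
                 severity = severity$severity[match(ev, severity$year)]),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("Drought event set (", x$variable, ", ", x$site, "): ",
      paste(x$years, collapse = ", "), "\n", sep = "")
  invisible(x)
}
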