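#' Cubic smoothing spline detrending with a 50\% frequency cutoff
#'
#' Fits a stiffness-penalized smoothing spline to an annual ring-width
#' series and returns the dimensionless tree-ring index (TRI), the ratio
#' between observed and fitted growth. The spline's stiffness is set from
#' the requested cutoff wavelength so that its amplitude frequency response
#' equals 0.5 at that wavelength: for the discrete second-difference
#' penalty the response at frequency \eqn{f} (cycles/year) is
#' \eqn{1 / (1 + \lambda (2 \sin \pi f)^4)}, hence
#' \eqn{\lambda = (2 \sin(\pi / P))^{-4}} for a cutoff period of \eqn{P}
#' years. This is the classical dendrochronological detrending spline used
#' to remove the age trend and other low-to-medium frequency variation
#' while preserving interannual variability.
#'
#' Missing rings (NA widths) are excluded from the fit; the penalty uses
#' second divided differences so unevenly spaced observed years are handled
#' consistently. Fitted values at gap years are not imputed.
#'
#' @param series a ring-width series as returned by [ring_width_series()]:
#'   a list with `tree_id`, `plot_id`, `years`, `widths` (mm, NA = missing
#'   ring).
#' @param wavelength_years cutoff wavelength in years at which the fitted
#'   curve retains 50\% of a sinusoid's amplitude (default 30).
#' @param on_nonpositive what to do if the fitted curve is not strictly
#'   positive: `"error"` (default) or `"mean"`, which falls back to
#'   horizontal-mean detrending for that series.
#' @return an object of class `"detrended_series"`: list with `tree_id`,
#'   `plot_id`, `years`, `widths`, `fitted` and `tri` (= widths / fitted).
#' @seealso [build_chronology()], [ring_width_series()]
#' @export
spline_detrend <- function(series, wavelength_years = 30,
                           on_nonpositive = c("error", "mean")) {
  on_nonpositive <- match.arg(on_nonpositive)
  stopifnot(is.numeric(series$widths), length(series$years) == length(series$widths))
  obs <- which(!is.na(series$widths))
  if (length(obs) < wavelength_years / 2) {
    stop("series '", series$tree_id, "' has ", length(obs),
         " observed rings; need at least wavelength/2 = ", wavelength_years / 2)
  }
  x <- as.numeric(series$years[obs])
  y <- series$widths[obs]
  if (any(y <= 0)) stop("ring widths must be strictly positive; got a value <= 0")
  lambda <- spline_lambda(wavelength_years)
  fit <- penalized_smooth(x, y, lambda)
  if (any(fit <= 0)) {
    if (on_nonpositive == "error") {
      stop("non-positive fitted value in spline detrend of series '",
           series$tree_id, "'")
    }
    fit <- rep(mean(y), length(y))
  }
  fitted <- rep(NA_real_, length(series$years))
  tri <- rep(NA_real_, length(series$years))
  fitted[obs] <- fit
  tri[obs] <- y / fit
  structure(list(tree_id = series$tree_id, plot_id = series$plot_id,
                 years = series$years, widths = series$widths,
                 fitted = fitted, tri = tri),
            class = "detrended_series")
}

#' Spline stiffness for a given cutoff wavelength
#'
#' @param wavelength_years cutoff period in years.
#' @return penalty weight lambda such that the smoother's amplitude
#'   response is 0.5 at that period.
#' @keywords internal
spline_lambda <- function(wavelength_years) {
  (2 * sin(pi / wavelength_years))^-4
}

# Solve min ||y - z||^2 + lambda * ||D z||^2 where D holds second divided
# differences over the (possibly unevenly spaced) abscissae x, scaled so
# that unit spacing reduces to the ordinary second difference.
penalized_smooth <- function(x, y, lambda) {
  n <- length(x)
  if (n < 3) return(rep(mean(y), n))
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  # second divided difference * mean spacing^2 -> second difference at h=1
  s <- (h1 + h2) / 2
  a <- 2 * s / (h1 * (h1 + h2))
  b <- -2 * s / (h1 * h2)
  d <- 2 * s / (h2 * (h1 + h2))
  D <- matrix(0, n - 2, n)
  idx <- seq_len(n - 2)
  D[cbind(idx, idx)] <- a
  D[cbind(idx, idx + 1)] <- b
  D[cbind(idx, idx + 2)] <- d
  A <- diag(n) + lambda * crossprod(D)
  as.vector(solve(A, y))
}

#' Tukey's biweight robust mean
#'
#' Iteratively reweighted biweight location estimate with tuning constant
#' 9 times the median absolute deviation (MAD about the median, unscaled).
#' Iterates the weighted-mean fixed point at most `max_iter` times or until
#' the relative change falls below `tol`. If the MAD is zero the median is
#' returned.
#'
#' @param x numeric vector (NAs dropped).
#' @param max_iter maximum fixed-point iterations (default 10).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @return the robust mean (scalar).
#' @export
tukey_biweight_mean <- function(x, max_iter = 10, tol = 1e-6) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no non-missing values")
  if (length(x) == 1) return(x)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  if (s == 0) return(m)
  c9 <- 9 * s
  for (i in seq_len(max_iter)) {
    u <- (x - m) / c9
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) <= tol * max(1, abs(m))) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m
}

#' Build a plot chronology from detrended series
#'
#' Averages the tree-level TRI series of one plot year by year using
#' Tukey's biweight robust mean, recording the sample depth (number of
#' trees contributing to each year). Years with fewer than `min_depth`
#' trees are dropped.
#'
#' @param detrended list of `"detrended_series"` objects (all from one plot).
#' @param plot_id plot identifier stored in the result.
#' @param min_depth minimum number of contributing trees per retained year
#'   (default 5).
#' @return an object of class `"chronology"`: list with `plot_id`, `years`,
#'   `index` and `sample_depth`.
#' @export
build_chronology <- function(detrended, plot_id, min_depth = 5) {
  if (length(detrended) == 0) stop("empty input: no detrended series")
  yrs <- sort(unique(unlist(lapply(detrended, function(d) d$years[!is.na(d$tri)]))))
  vals <- matrix(NA_real_, length(yrs), length(detrended))
  for (j in seq_along(detrended)) {
    d <- detrended[[j]]
    ok <- !is.na(d$tri)
    vals[match(d$years[ok], yrs), j] <- d$tri[ok]
  }
  depth <- rowSums(!is.na(vals))
  keep <- depth >= min_depth
  if (!any(keep)) stop("no year reaches the minimum sample depth of ", min_depth)
  index <- apply(vals[keep, , drop = FALSE], 1, tukey_biweight_mean)
  structure(list(plot_id = plot_id, years = yrs[keep], index = index,
                 sample_depth = depth[keep]),
            class = "chronology")
}

#' Construct a ring-width series
#'
#' @param tree_id,plot_id identifiers.
#' @param first_year calendar year of the first ring.
#' @param widths annual ring widths in mm; NA marks a missing ring.
#' @return an object of class `"ring_width_series"`.
#' @export
ring_width_series <- function(tree_id, plot_id, first_year, widths) {
  stopifnot(length(first_year) == 1, is.numeric(widths), length(widths) >= 1)
  if (any(widths <= 0, na.rm = TRUE)) {
    stop("ring widths must be > 0 (use NA for missing rings)")
  }
  structure(list(tree_id = as.character(tree_id),
                 plot_id = as.character(plot_id),
                 first_year = as.integer(first_year),
                 years = as.integer(first_year) + seq_along(widths) - 1L,
                 widths = as.numeric(widths)),
            class = "ring_width_series")
}

#' @export
print.chronology <- function(x, ...) {
  cat("Plot chronology", x$plot_id, "\n")
  cat("  years:", min(x$years), "-", max(x$years),
      " mean index:", round(mean(x$index), 3),
      " mean depth:", round(mean(x$sample_depth), 1), "\n")
  invisible(x)
}

#' Export chronologies to a tidy data frame
#'
#' @param chronologies list of `"chronology"` objects.
#' @return data.frame with columns plot_id, year, index, sample_depth.
#' @export
chronology_table <- function(chronologies) {
  do.call(rbind, lapply(chronologies, function(ch) {
    data.frame(plot_id = ch$plot_id, year = ch$years, index = ch$index,
               sample_depth = ch$sample_depth, row.names = NULL)
  }))
}
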