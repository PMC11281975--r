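#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red). Vectorized; where both reflectances
#' are zero the index is undefined and NA is returned.
#'
#' @param nir,red reflectances (>= 0).
#' @return NDVI values in [-1, 1] (NA where undefined).
#' @export
compute_ndvi <- function(nir, red) {
  stopifnot(all(nir >= 0, na.rm = TRUE), all(red >= 0, na.rm = TRUE))
  s <- nir + red
  out <- ifelse(s == 0, NA_real_, (nir - red) / s)
  out
}

#' Thermal growing-season window for one year
#'
#' The season starts on the first day of year d (d >= 6) whose five
#' preceding days (d-5 .. d-1) have mean temperature strictly above the
#' species threshold (12 degC for Scots pine, 9 degC for Norway spruce;
#' these trigger bud burst at comparable elevations). The season ends on
#' 30 September of the same calendar year. If no day qualifies on or
#' before the end date the season is empty and flagged.
#'
#' @param daily_T data.frame with `year`, `doy`, `T` covering the year from
#'   DOY 1.
#' @param year calendar year.
#' @param threshold temperature threshold in degC.
#' @return list with `start_doy`, `end_doy`, `empty` (logical).
#' @export
growing_season_window <- function(daily_T, year, threshold) {
  sel <- daily_T$year == year
  doy <- daily_T$doy[sel]
  tt <- daily_T$T[sel][order(doy)]
  doy <- sort(doy)
  if (length(doy) == 0 || doy[1] != 1 || any(diff(doy) != 1)) {
    stop("daily temperature must cover year ", year, " contiguously from DOY 1")
  }
  end_doy <- if (is_leap(year)) 274L else 273L  # 30 September
  start <- NA_integer_
  for (d in 6:min(length(tt), end_doy)) {
    if (mean(tt[(d - 5):(d - 1)]) > threshold) {
      start <- d
      break
    }
  }
  if (is.na(start) || start > end_doy) {
    return(list(start_doy = NA_integer_, end_doy = end_doy, empty = TRUE))
  }
  list(start_doy = as.integer(start), end_doy = end_doy, empty = FALSE)
}

#' Annual per-pixel median NDVI composite
#'
#' Computes each pixel's NDVI per scene, restricts to unmasked
#' observations acquired within the growing-season window of the given
#' year, and takes the per-pixel median (even counts average the two
#' middle values). Pixels with no usable observation get NA.
#'
#' @param scenes data.frame with columns `date` (Date), `pixel_id`, `red`,
#'   `nir`, `cloud_flag` (logical or 0/1).
#' @param window list with `start_doy`, `end_doy` as returned by
#'   [growing_season_window()].
#' @param year calendar year.
#' @return data.frame with `pixel_id`, `ndvi`.
#' @export
annual_median_composite <- function(scenes, window, year) {
  doy <- as.integer(strftime(scenes$date, "%j"))
  yr <- as.integer(strftime(scenes$date, "%Y"))
  if (isTRUE(window$empty)) {
    keep <- rep(FALSE, nrow(scenes))
  } else {
    keep <- yr == year & doy >= window$start_doy & doy <= window$end_doy &
      !as.logical(scenes$cloud_flag)
  }
  px <- sort(unique(scenes$pixel_id))
  nd <- compute_ndvi(scenes$nir, scenes$red)
  med <- vapply(px, function(p) {
    v <- nd[keep & scenes$pixel_id == p]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  data.frame(pixel_id = px, ndvi = med)
}

#' Overlap-weighted plot value from per-pixel composites
#'
#' Weighted mean of the pixel composites, weights proportional to the
#' fraction of the plot area falling in each pixel. Weights are
#' renormalized over non-missing pixels; if every pixel is missing the
#' result is NA.
#'
#' @param composite data.frame with `pixel_id`, `ndvi`.
#' @param weights named numeric vector (names = pixel ids), >= 0 with at
#'   least one positive entry.
#' @return scalar plot NDVI (NA if no usable pixel).
#' @export
extract_plot_value <- function(composite, weights) {
  stopifnot(all(weights >= 0), any(weights > 0))
  w <- weights[match(composite$pixel_id, names(weights))]
  ok <- !is.na(composite$ndvi) & !is.na(w) & w > 0
  if (!any(ok)) return(NA_real_)
  w <- w[ok] / sum(w[ok])
  sum(w * composite$ndvi[ok])
}

#' Linear detrending of an annual NDVI series
#'
#' Fits an ordinary least-squares line of NDVI on calendar year and stores
#' the residuals. The slow linear drift in conifer NDVI (canopy closure,
#' CO2 fertilization) is removed so that interannual anomalies remain.
#'
#' @param years calendar years.
#' @param ndvi annual plot NDVI values (NA allowed).
#' @param plot_id identifier stored in the result.
#' @return an object of class `"annual_greenness"`: list with `plot_id`,
#'   `years`, `ndvi`, `residual`, `trend` (slope per year).
#' @export
detrend_linear_residuals <- function(years, ndvi, plot_id = "plot") {
  ok <- !is.na(ndvi)
  if (sum(ok) < 3) stop("need at least 3 non-missing years to fit a trend")
  fit <- stats::lm(ndvi ~ years, data = data.frame(years = years, ndvi = ndvi))
  res <- rep(NA_real_, length(years))
  res[ok] <- stats::residuals(fit)
  structure(list(plot_id = plot_id, years = years, ndvi = ndvi,
                 residual = res, trend = unname(stats::coef(fit)[2])),
            class = "annual_greenness")
}
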