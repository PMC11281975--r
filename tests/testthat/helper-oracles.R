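# Independent oracle implementations used to cross-check the package code.
# These are deliberately written with different machinery than the package
# (dense linear algebra, explicit loops, enumeration).

# direct fixed-point biweight iteration (c = 9 * MAD about the median,
# scale held fixed), run to convergence
oracle_biweight <- function(x, iters = 50) {
  m0 <- median(x)
  s <- median(abs(x - m0))
  if (s == 0) return(m0)
  m <- m0
  for (i in seq_len(iters)) {
    u <- (x - m) / (9 * s)
    w <- pmax(0, 1 - u^2)^2
    m <- sum(w * x) / sum(w)
  }
  m
}

# dense solve of the penalized least-squares system for an equally spaced
# series, with the D matrix built by diff() and solved by qr
oracle_spline_fit <- function(y, wavelength) {
  n <- length(y)
  lambda <- 1 / (2 * sin(pi / wavelength))^4
  D <- diff(diag(n), differences = 2)
  qr.solve(diag(n) + lambda * crossprod(D), y)
}

# published Thornthwaite equations evaluated directly for one year of
# monthly temperatures (lat in degrees)
oracle_thornthwaite <- function(Tm, lat, year = 2001) {
  I <- sum((pmax(Tm, 0) / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  mid <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  leap <- (year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0
  if (leap) { dm[2] <- 29 }
  pet <- numeric(12)
  for (m in 1:12) {
    if (Tm[m] <= 0) next
    pe <- if (Tm[m] < 26.5) 16 * (10 * Tm[m] / I)^a else
      -415.85 + 32.24 * Tm[m] - 0.43 * Tm[m]^2
    delta <- 0.409 * sin(2 * pi * mid[m] / 365 - 1.39)
    ws <- acos(min(1, max(-1, -tan(lat * pi / 180) * tan(delta))))
    N <- 24 / pi * ws
    pet[m] <- pe * (N / 12) * (dm[m] / 30)
  }
  pet
}

# exhaustive search over all size-n non-consecutive subsets maximizing
# total severity
oracle_best_nonconsecutive <- function(years, sev, n) {
  combs <- combn(seq_along(years), n)
  best <- NULL
  best_tot <- -Inf
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    if (any(diff(years[idx]) == 1)) next
    tot <- sum(sev[idx])
    if (tot > best_tot) {
      best_tot <- tot
      best <- years[idx]
    }
  }
  list(years = best, total = best_tot)
}

# closed-form simple linear regression residuals
oracle_ols_residuals <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  y - (a + b * x)
}

# tiny deterministic ring-width fixture
make_series <- function(widths, first_year = 1900, id = "T01", plot = "P1") {
  ring_width_series(id, plot, first_year, widths)
}
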