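test_that("Thornthwaite PET matches the published equations", {
  cl <- expand.grid(month = 1:12, year = 2001)
  cl$T <- 10
  out <- thornthwaite_pet(cl, 0)
  # at the equator with constant T = 10: 48.9 mm per standard 30-day month
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expect_lt(max(abs(out$PET / dm * 30 - 48.9)), 0.5)
  expect_lt(max(abs(out$PET - oracle_thornthwaite(rep(10, 12), 0))), 0.5)

  # realistic mid-latitude seasonal cycle against the oracle
  Tm <- 7 + 10 * sin(2 * pi * ((1:12) - 3.5) / 12)
  cl$T <- Tm
  out <- thornthwaite_pet(cl, 49.5)
  expect_lt(max(abs(out$PET - oracle_thornthwaite(Tm, 49.5))), 1e-8)
})

test_that("PET is zero for freezing months and non-decreasing in temperature", {
  cl <- expand.grid(month = 1:12, year = 2001)
  cl$T <- c(-5, -3, 0, 2, 8, 14, 17, 16, 11, 6, 1, -2)
  out <- thornthwaite_pet(cl, 49.5)
  expect_true(all(out$PET[cl$T <= 0] == 0))

  # vary only July (the rest of the heat-index inputs held fixed)
  Tm <- 7 + 10 * sin(2 * pi * ((1:12) - 3.5) / 12)
  pets <- sapply(seq(4, 26, by = 2), function(tj) {
    cl$T <- Tm
    cl$T[7] <- tj
    thornthwaite_pet(cl, 49.5)$PET[7]
  })
  expect_true(all(diff(pets) > 0))
  expect_error(thornthwaite_pet(cl, 95), "latitude")
})

stationary_climate <- function(seed = 5, years = 1985:2017) {
  set.seed(seed)
  mon <- expand.grid(month = 1:12, year = years)
  mon$T <- 7 + 10 * sin(2 * pi * (mon$month - 3.5) / 12) + rnorm(nrow(mon), 0, 1.5)
  mon$P <- pmax(0, 70 + 20 * sin(2 * pi * (mon$month - 3.5) / 12) +
                  rnorm(nrow(mon), 0, 15))
  thornthwaite_pet(mon, 49.5)
}

test_that("the accumulated water balance equals a brute-force rolling sum", {
  mon <- stationary_climate()
  out <- spei(mon, scale = 4)
  d <- out$P - out$PET
  acc <- sapply(4:length(d), function(i) sum(d[(i - 3):i]))
  expect_equal(out$D_acc[4:length(d)], acc, tolerance = 1e-10)
  expect_true(all(is.na(out$D_acc[1:3])))
})

test_that("SPEI is standardized per calendar month over the calibration period", {
  out <- spei(stationary_climate(), scale = 4, calibration = 1985:2017)
  by_m <- split(out$SPEI[!is.na(out$SPEI)], out$month[!is.na(out$SPEI)])
  means <- sapply(by_m, mean)
  sds <- sapply(by_m, sd)
  expect_lt(max(abs(means)), 0.05)
  expect_lt(max(abs(sds - 1)), 0.1)
})

test_that("SPEI is monotone in the accumulated balance and shift-invariant", {
  mon <- stationary_climate(9)
  out <- spei(mon, scale = 4)
  # within one calendar month, ordering by D_acc equals ordering by SPEI
  for (m in c(2, 7, 11)) {
    sel <- out$month == m & !is.na(out$SPEI)
    expect_equal(order(out$D_acc[sel]), order(out$SPEI[sel]))
  }
  # adding the same constant to P and PET leaves D and hence SPEI unchanged
  mon2 <- mon
  mon2$P <- mon2$P + 37
  mon2$PET <- mon2$PET + 37
  out2 <- spei(mon2, scale = 4)
  expect_equal(out2$SPEI, out$SPEI, tolerance = 1e-10)
})

test_that("degenerate accumulated series raise a month-naming error", {
  mon <- expand.grid(month = 1:12, year = 1985:2017)
  mon$P <- 50
  mon$PET <- 20
  expect_error(spei(mon, scale = 4), "month 1|constant")
})

test_that("seasonal means average the season months and flag gaps", {
  mon <- expand.grid(month = 1:12, year = 2000:2001)
  mon$T <- rep(c(10, 20, 30), length.out = nrow(mon))
  mon$T[mon$month %in% 6:8 & mon$year == 2000] <- c(10, 20, 30)
  s <- seasonal_means(mon, "JJA", "T")
  expect_equal(s$T[s$year == 2000], 20)
  gs <- seasonal_means(transform(mon, T = 5), "GS", "T")
  expect_equal(gs$T, c(5, 5))
  # single-month season is the identity
  one <- seasonal_means(mon, 7, "T")
  expect_equal(one$T[one$year == 2000], mon$T[mon$month == 7 & mon$year == 2000])
  # missing month -> NA year
  mon2 <- mon[!(mon$year == 2001 & mon$month == 7), ]
  s2 <- seasonal_means(mon2, "JJA", "T")
  expect_true(is.na(s2$T[s2$year == 2001]))
})

test_that("severity anomalies standardize against the baseline", {
  s <- data.frame(year = 2000:2012, SR = c(rep(c(8, 12), 6), 10))
  sev <- severity_anomalies(s, "SR", baseline = 2000:2011)
  # a year sitting exactly at the baseline mean has zero severity
  expect_equal(sev$severity[13], 0)
  set.seed(11)
  s2 <- data.frame(year = 1985:2017, SR = rnorm(33, 100, 7))
  sev2 <- severity_anomalies(s2, "SR")
  expect_lt(abs(mean(sev2$severity)), 1e-12)
  expect_equal(sd(sev2$severity), 1, tolerance = 1e-12)
  # location invariance
  sev3 <- severity_anomalies(transform(s2, SR = SR + 55), "SR")
  expect_equal(sev3$severity, sev2$severity, tolerance = 1e-10)
  expect_error(severity_anomalies(s2[1:4, ], "SR"), "5 years")
})

test_that("drought-year selection is greedy, non-consecutive and matches enumeration", {
  yrs <- 2000:2017
  sev <- rep(0, 18)
  sev[match(c(2002, 2003, 2010, 2015, 2016), yrs)] <- c(3.0, 2.9, 2.5, 2.0, 1.9)
  es <- select_drought_years(data.frame(year = yrs, severity = sev), n = 4)
  expect_true(all(c(2002, 2010, 2015) %in% es$years))
  expect_false(any(c(2003, 2016) %in% es$years))
  expect_true(all(diff(es$years) > 1))
  # total severity agrees with exhaustive search over non-consecutive 4-subsets
  br <- oracle_best_nonconsecutive(yrs, sev, 4)
  expect_equal(sum(sev[match(es$years, yrs)]), br$total)
  # tie toward the earlier year: the fourth pick is the earliest zero year
  expect_equal(setdiff(es$years, c(2002, 2010, 2015)), 2000)

  # four well-separated maxima are picked exactly; n = 1 takes the extreme
  sev2 <- rep(0, 18)
  sev2[match(c(2001, 2005, 2009, 2013), yrs)] <- 2
  es2 <- select_drought_years(data.frame(year = yrs, severity = sev2), n = 4)
  expect_equal(es2$years, c(2001, 2005, 2009, 2013))
  es1 <- select_drought_years(data.frame(year = yrs, severity = sev), n = 1)
  expect_equal(es1$years, 2002)
  # direction = "min" flips the criterion
  esm <- select_drought_years(data.frame(year = yrs, severity = -sev), n = 1,
                              direction = "min")
  expect_equal(esm$years, 2002)
})

test_that("event sets from random severities are always non-consecutive", {
  set.seed(13)
  for (i in 1:25) {
    sev <- data.frame(year = 1985:2017, severity = rnorm(33))
    es <- select_drought_years(sev, n = 4)
    expect_true(all(diff(es$years) > 1))
  }
  expect_error(select_drought_years(data.frame(year = 2000:2002,
                                               severity = c(1, 2, 3)), n = 3),
               "non-consecutive")
})
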