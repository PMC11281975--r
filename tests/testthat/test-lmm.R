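sim_lmm_data <- function(n_per_group = 100, groups = 4, beta = c(0.1, -0.05, -0.03),
                         sd_b = 0.02, sd_e = 0.05) {
  n <- n_per_group * groups
  g <- factor(rep(seq_len(groups), each = n_per_group))
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  b <- rnorm(groups, 0, sd_b)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + b[g] + rnorm(n, 0, sd_e)
  data.frame(y = y, x1 = x1, x2 = x2, g = g)
}

test_that("REML fit agrees with lme4 on likelihood, effects and variances", {
  skip_if_not_installed("lme4")
  set.seed(71)
  d <- sim_lmm_data(sd_b = 0.3, sd_e = 0.5)
  f <- lmm_ri(y ~ x1 + x2, d, "g")
  m <- lme4::lmer(y ~ x1 + x2 + (1 | g), d, REML = TRUE)
  expect_equal(f$logLik_REML, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(f$AIC, stats::AIC(m), tolerance = 1e-6)
  expect_equal(unname(f$coefficients), unname(lme4::fixef(m)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma2_b, vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(stats::vcov(m))))),
               tolerance = 1e-5)
  expect_equal(unname(f$marginal_residuals - f$ranef[as.character(d$g)]),
               f$residuals, tolerance = 1e-10)
})

test_that("zero group variance collapses to ordinary least squares", {
  set.seed(72)
  d <- sim_lmm_data(sd_b = 0, sd_e = 0.05)
  # make the realized group effects exactly zero so the REML boundary
  # estimate is pinned at zero rather than left to sampling luck
  d$y <- d$y - stats::ave(d$y, d$g) + mean(d$y)
  f <- lmm_ri(y ~ x1 + x2, d, "g")
  ols <- stats::lm(y ~ x1 + x2, d)
  expect_lte(f$sigma2_b, 1e-6)
  expect_true(f$singular)
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("balanced two-group REML matches the one-way ANOVA closed form", {
  set.seed(73)
  m_per <- 30
  g <- factor(rep(1:2, each = m_per))
  y <- c(rnorm(m_per, 0, 1), rnorm(m_per, 2, 1))
  d <- data.frame(y = y, g = g)
  f <- lmm_ri(y ~ 1, d, "g")
  gm <- tapply(y, g, mean)
  msw <- sum((y - gm[g])^2) / (length(y) - 2)
  msb <- m_per * sum((gm - mean(gm))^2) / (2 - 1)
  expect_equal(f$sigma2, msw, tolerance = 1e-6)
  expect_equal(f$sigma2_b, (msb - msw) / m_per, tolerance = 1e-6)
})

test_that("parameter recovery: estimates cover the truth in >= 90% of replicates", {
  set.seed(74)
  R <- 200
  hits <- matrix(FALSE, R, 4)
  for (r in seq_len(R)) {
    d <- sim_lmm_data()
    f <- lmm_ri(y ~ x1 + x2, d, "g")
    ci <- confint(f)
    hits[r, 1] <- ci["x1", 1] <= -0.05 && -0.05 <= ci["x1", 2]
    hits[r, 2] <- ci["x2", 1] <= -0.03 && -0.03 <= ci["x2", 2]
    hits[r, 3] <- ci["sigma2_b", 1] <= 0.02^2 && 0.02^2 <= ci["sigma2_b", 2]
    hits[r, 4] <- ci["sigma2", 1] <= 0.05^2 && 0.05^2 <= ci["sigma2", 2]
  }
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("model metrics collapse and saturate as the definitions require", {
  set.seed(75)
  d <- sim_lmm_data(sd_b = 0, sd_e = 0.05)
  f <- lmm_ri(y ~ x1 + x2, d, "g")
  m <- model_metrics(f)
  expect_equal(m$r2_marginal, m$r2_conditional, tolerance = 1e-8)
  # noise-free linear data: all three R2 reach 1
  d2 <- d
  d2$y <- 0.2 + 0.5 * d2$x1 - 0.1 * d2$x2
  f2 <- lmm_ri(y ~ x1 + x2, d2, "g")
  m2 <- model_metrics(f2)
  expect_equal(m2$r2_marginal, 1, tolerance = 1e-6)
  expect_equal(m2$pseudo_r2, 1, tolerance = 1e-6)
  expect_gte(m2$r2_conditional, m2$r2_marginal - 1e-10)
})

test_that("variance shares map onto marginal and conditional R2", {
  set.seed(76)
  n_g <- 100; m <- 20
  g <- factor(rep(seq_len(n_g), each = m))
  x <- rnorm(n_g * m)
  b <- rnorm(n_g, 0, sqrt(0.2))
  y <- sqrt(0.3) * x + b[g] + rnorm(n_g * m, 0, sqrt(0.5))
  f <- lmm_ri(y ~ x, data.frame(y, x, g), "g")
  mm <- model_metrics(f)
  expect_lt(abs(mm$r2_marginal - 0.3), 0.05)
  expect_lt(abs(mm$r2_conditional - 0.5), 0.05)
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(77)
  n <- 500
  x1 <- rnorm(n)
  x2 <- scale(0.5 * scale(x1) + sqrt(0.75) * scale(resid(lm(rnorm(n) ~ x1))))
  X <- cbind(x1 = x1, x2 = as.vector(x2))
  r <- cor(X)[1, 2]
  v <- vif(X)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  # exactly orthogonal centered predictors: VIF = 1
  Xo <- stats::poly(1:100, 3)
  expect_equal(unname(vif(Xo)), rep(1, 3), tolerance = 1e-10)
  # duplicated column: infinite VIF
  expect_true(any(is.infinite(vif(cbind(x1, x1)))))
})

test_that("VIF agrees with the standard regression-based implementation", {
  skip_if_not_installed("car")
  set.seed(78)
  d <- sim_lmm_data(sd_b = 0.1, sd_e = 0.3)
  lmfit <- stats::lm(y ~ x1 + x2, d)
  v_ref <- car::vif(lmfit)
  v <- vif(cbind(x1 = d$x1, x2 = d$x2))
  expect_equal(unname(v), unname(v_ref), tolerance = 1e-8)
})

test_that("random-effect LRT is non-negative, calibrated under the null, powered", {
  set.seed(79)
  R <- 200
  p_null <- p_alt <- stat_null <- numeric(R)
  for (r in seq_len(R)) {
    d0 <- sim_lmm_data(n_per_group = 25, sd_b = 0, sd_e = 0.05)
    f0 <- lmm_ri(y ~ x1 + x2, d0, "g")
    l0 <- random_effect_lrt(f0)
    stat_null[r] <- l0$statistic
    p_null[r] <- l0$p
    d1 <- sim_lmm_data(n_per_group = 100, sd_b = 0.05, sd_e = 0.05)
    p_alt[r] <- random_effect_lrt(lmm_ri(y ~ x1 + x2, d1, "g"))$p
  }
  expect_true(all(stat_null >= 0))
  expect_gte(mean(p_null > 0.05), 0.9)
  expect_gte(mean(p_alt < 0.01), 0.9)
})

test_that("random-effect LRT matches lmerTest's ranova statistic", {
  skip_if_not_installed("lmerTest")
  set.seed(80)
  d <- sim_lmm_data(sd_b = 0.1, sd_e = 0.2)
  f <- lmm_ri(y ~ x1 + x2, d, "g")
  l <- random_effect_lrt(f)
  m <- lmerTest::lmer(y ~ x1 + x2 + (1 | g), d, REML = TRUE)
  rv <- lmerTest::ranova(m)
  expect_equal(l$statistic, rv$LRT[2], tolerance = 1e-4)
})

test_that("the generating model variant attains the lowest AIC most of the time", {
  set.seed(81)
  R <- 200
  wins <- signs <- r2drop <- logical(R)
  for (r in seq_len(R)) {
    # both severities act: the full model is the generating one
    n <- 400
    g <- factor(rep(1:4, each = 100))
    sev0 <- rnorm(n); sev <- rnorm(n)
    y <- -0.05 * sev0 - 0.03 * sev + rnorm(4, 0, 0.02)[g] + rnorm(n, 0, 0.05)
    tb <- data.frame(response = y, sev0 = sev0, sev = sev, category = g)
    fm <- fit_response_models(tb)
    wins[r] <- fm$summary$variant[which.min(fm$summary$AIC)] == "full"
    signs[r] <- fm$summary$t_sev0[1] < 0 && fm$summary$t_sev[1] < 0
    r2drop[r] <- fm$summary$r2_marginal[fm$summary$variant == "without_SEV0"] <
      fm$summary$r2_marginal[fm$summary$variant == "full"]
  }
  expect_gte(mean(wins), 0.8)
  expect_gte(mean(signs), 0.95)
  expect_true(all(r2drop))
})

test_that("resilience metrics satisfy the Lloret identities", {
  # worked toy: pre 1.0, event 0.5, post 0.75
  yrs <- 2000:2010
  vals <- rep(1, 11)
  vals[6] <- 0.5
  vals[7:9] <- 0.75
  r <- resilience_metrics(yrs, vals, 2005)
  expect_equal(r$resistance, 0.5)
  expect_equal(r$recovery, 1.5)
  expect_equal(r$resilience, 0.75)
  # flat series: all metrics are 1
  rf <- resilience_metrics(yrs, rep(0.8, 11), 2005)
  expect_equal(c(rf$resistance, rf$recovery, rf$resilience), c(1, 1, 1))
  # identity on random valid inputs
  set.seed(82)
  for (i in 1:50) {
    v <- runif(11, 0.3, 2)
    r <- resilience_metrics(yrs, v, 2005)
    expect_lt(abs(r$resilience - r$resistance * r$recovery), 1e-12)
  }
  expect_error(resilience_metrics(yrs, vals, 2002), "window")
  v0 <- vals; v0[6] <- 0
  expect_error(resilience_metrics(yrs, replace(vals, 6, NA), 2005), "missing|zero")
})

test_that("excluding other event years shifts the resilience windows", {
  yrs <- 2000:2012
  vals <- rep(1, 13)
  vals[7] <- 0.5     # event 2006
  vals[5] <- 0.2     # another event 2004 inside the pre window
  r_with <- resilience_metrics(yrs, vals, 2006)
  r_excl <- resilience_metrics(yrs, vals, 2006, exclude_years = 2004)
  expect_lt(r_with$pre_mean, r_excl$pre_mean)
  expect_equal(r_excl$pre_mean, 1)
})
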