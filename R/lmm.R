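#' Random-intercept linear mixed model by REML
#'
#' Fits \eqn{y = X\beta + Z b + \epsilon} with a single random intercept
#' per group (\eqn{b_g \sim N(0, \sigma^2_b)}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}) by restricted maximum likelihood. The REML criterion is
#' profiled down to a one-dimensional optimization over the variance ratio
#' \eqn{\gamma = \sigma^2_b / \sigma^2}; for fixed \eqn{\gamma} the GLS
#' fixed effects and the residual variance have closed forms obtained from
#' group-level sufficient statistics, so the fit is exact and fast for any
#' number of rows. A variance ratio estimated at the zero boundary is
#' reported via the `singular` flag, not an error.
#'
#' Fixed-effect p-values use the large-sample normal reference.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `response ~ sev0 + sev`.
#' @param data data.frame with the model variables.
#' @param group name of the grouping column (random intercept), e.g.
#'   `"category"`.
#' @return an object of class `"lmm_ri"` with components `coefficients`,
#'   `se`, `tvalues`, `pvalues`, `sigma2` (residual variance), `sigma2_b`
#'   (random-intercept variance), `gamma` (ratio), `logLik_REML`, `AIC`,
#'   `fitted` (including group effects), `residuals`, `ranef`, `singular`,
#'   `n`, `groups`, plus the call, formula and model frame.
#' @seealso [model_metrics()], [random_effect_lrt()], [vif()]
#' @export
lmm_ri <- function(formula, data, group) {
  vars <- all.vars(formula)
  stopifnot(group %in% names(data))
  dat <- data[stats::complete.cases(data[, c(vars, group), drop = FALSE]), ,
              drop = FALSE]
  mf <- stats::model.frame(formula, data = dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = mf)
  g <- droplevels(factor(dat[[group]]))
  if (nlevels(g) < 2) stop("need at least 2 groups for a random intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("fixed-effect predictors are perfectly collinear")

  prof <- function(loggamma) reml_profile(exp(loggamma), X, y, g)$neg2rl
  opt <- stats::optimize(prof, interval = c(-14, 14), tol = 1e-9)
  cand_gamma <- exp(opt$minimum)
  at0 <- reml_profile(0, X, y, g)
  atg <- reml_profile(cand_gamma, X, y, g)
  if (at0$neg2rl <= atg$neg2rl + 1e-10) {
    gamma_hat <- 0
    best <- at0
  } else {
    gamma_hat <- cand_gamma
    best <- atg
  }
  beta <- best$beta
  sigma2 <- best$sigma2
  sigma2_b <- gamma_hat * sigma2
  se <- sqrt(diag(best$cov_beta))
  tv <- beta / se
  pv <- 2 * stats::pnorm(-abs(tv))
  # BLUPs: b_g = gamma/(1 + n_g gamma) * sum of marginal residuals in group
  r <- as.vector(y - X %*% beta)
  ng <- tabulate(g)
  sums <- as.vector(tapply(r, g, sum))
  bg <- gamma_hat / (1 + ng * gamma_hat) * sums
  names(bg) <- levels(g)
  fitted <- as.vector(X %*% beta) + unname(bg)[as.integer(g)]
  p <- ncol(X)
  ll <- -0.5 * best$neg2rl
  npar <- p + 2  # fixed effects + two variance components
  structure(list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 tvalues = stats::setNames(tv, colnames(X)),
                 pvalues = stats::setNames(pv, colnames(X)),
                 sigma2 = sigma2, sigma2_b = sigma2_b, gamma = gamma_hat,
                 logLik_REML = ll, AIC = -2 * ll + 2 * npar,
                 fitted = fitted, residuals = as.vector(y) - fitted,
                 marginal_residuals = r,
                 ranef = bg, singular = gamma_hat <= 1e-8,
                 n = length(y), groups = levels(g), group_var = group,
                 X = X, y = as.vector(y), g = g,
                 formula = formula, call = match.call()),
            class = "lmm_ri")
}

# Profiled REML pieces for a given variance ratio gamma, using the
# block structure (I + gamma * 1 1')^{-1} = I - gamma/(1 + n_g gamma) 1 1'
# within each group.
reml_profile <- function(gamma, X, y, g) {
  n <- nrow(X)
  p <- ncol(X)
  ng <- tabulate(g)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  Xg <- rowsum(X, g)                    # group sums of columns of X
  yg <- as.vector(rowsum(y, g))
  a <- gamma / (1 + ng * gamma)
  XtWX <- XtX - crossprod(Xg * sqrt(a))
  XtWy <- Xty - t(Xg) %*% (a * yg)
  ytWy <- yty - sum(a * yg^2)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- ytWy - sum(XtWy * beta)
  rss <- max(rss, 1e-300)
  sigma2 <- rss / (n - p)
  logdetV0 <- sum(log1p(ng * gamma))
  logdetXtWX <- 2 * sum(log(diag(ch)))
  # Harville REML log-likelihood, profiled over sigma^2
  neg2rl <- (n - p) * (log(2 * pi) + log(sigma2) + 1) + logdetV0 + logdetXtWX
  cov_beta <- sigma2 * chol2inv(ch)
  list(neg2rl = neg2rl, beta = as.vector(beta), sigma2 = sigma2,
       cov_beta = cov_beta)
}

#' @export
print.lmm_ri <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  formula:", deparse(x$formula), "  group:", x$group_var, "\n")
  cat("  n =", x$n, " groups =", length(x$groups),
      if (x$singular) " [singular: zero group variance]" else "", "\n")
  cat("  REML logLik:", format(x$logLik_REML, digits = 6),
      " AIC:", format(x$AIC, digits = 6), "\n")
  cat("  sigma_b =", format(sqrt(x$sigma2_b), digits = 4),
      " sigma =", format(sqrt(x$sigma2), digits = 4), "\n")
  cat("Fixed effects:\n")
  print(round(cbind(Estimate = x$coefficients, `Std.Error` = x$se,
                    t = x$tvalues, p = x$pvalues), 4))
  invisible(x)
}

#' @export
summary.lmm_ri <- function(object, ...) {
  m <- model_metrics(object)
  out <- list(fit = object, metrics = m)
  class(out) <- "summary.lmm_ri"
  out
}

#' @export
print.summary.lmm_ri <- function(x, ...) {
  print(x$fit)
  cat("R2 marginal:", round(x$metrics$r2_marginal, 3),
      " R2 conditional:", round(x$metrics$r2_conditional, 3),
      " pseudo-R2:", round(x$metrics$pseudo_r2, 3), "\n")
  invisible(x)
}

#' @export
coef.lmm_ri <- function(object, ...) object$coefficients

#' @export
fitted.lmm_ri <- function(object, ...) object$fitted

#' @export
residuals.lmm_ri <- function(object, ...) object$residuals

#' @export
logLik.lmm_ri <- function(object, ...) {
  structure(object$logLik_REML, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
vcov.lmm_ri <- function(object, ...) {
  ch <- chol(crossprod_weighted(object))
  object$sigma2 * chol2inv(ch)
}

crossprod_weighted <- function(object) {
  ng <- tabulate(object$g)
  a <- object$gamma / (1 + ng * object$gamma)
  Xg <- rowsum(object$X, object$g)
  crossprod(object$X) - crossprod(Xg * sqrt(a))
}

#' @export
predict.lmm_ri <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           data = newdata)
  eta <- as.vector(X %*% object$coefficients)
  if (!is.null(re.form) && !identical(re.form, NA)) return(eta)
  if (object$group_var %in% names(newdata)) {
    b <- object$ranef[as.character(newdata[[object$group_var]])]
    b[is.na(b)] <- 0
    eta <- eta + b
  }
  eta
}

#' Confidence intervals for a random-intercept mixed model
#'
#' Wald intervals for the fixed effects; a profile-REML interval for the
#' random-intercept variance (the one-dimensional REML profile over the
#' variance ratio is inverted at the chi-square(1) critical value, with
#' the lower bound clamped at the zero boundary); a chi-square interval
#' for the residual variance.
#'
#' @param object an [lmm_ri()] fit.
#' @param parm ignored (all parameters returned).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return matrix with rows for each fixed effect, `sigma2_b` and
#'   `sigma2`; columns `lower`, `upper`.
#' @export
confint.lmm_ri <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  fe <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  crit <- stats::qchisq(level, 1)
  n2 <- -2 * object$logLik_REML
  h <- function(g) reml_profile(g, object$X, object$y, object$g)$neg2rl - n2 - crit
  hi <- max(object$gamma, 1e-6)
  while (h(hi) < 0 && hi < 1e6) hi <- hi * 4
  up_g <- if (h(hi) < 0) hi else
    stats::uniroot(h, c(max(object$gamma, 1e-8), hi))$root
  lo_g <- if (h(0) <= 0) 0 else
    stats::uniroot(h, c(1e-12, max(object$gamma, 1e-8)))$root
  s2_at <- function(g) reml_profile(g, object$X, object$y, object$g)$sigma2
  vb <- c(lo_g * s2_at(lo_g), up_g * s2_at(up_g))
  np <- object$n - length(object$coefficients)
  vs <- np * object$sigma2 / stats::qchisq(c((1 + level) / 2, (1 - level) / 2), np)
  out <- rbind(fe, sigma2_b = vb, sigma2 = vs)
  colnames(out) <- c("lower", "upper")
  out
}

#' Fit metrics for a random-intercept mixed model
#'
#' Variance-partition R-squared statistics in the Nakagawa-Schielzeth
#' sense: marginal R2 = var(fixed-effect predictions) divided by the sum
#' of fixed-effect, random-intercept and residual variances; conditional
#' R2 adds the random-intercept variance to the numerator; pseudo-R2 is
#' the squared Pearson correlation between observed values and fitted
#' values including the group effects. Residual normality is summarized as
#' the correlation between sample and theoretical normal quantiles of the
#' residuals (a numerical q-q check).
#'
#' @param fit an [lmm_ri()] fit.
#' @return list with `r2_marginal`, `r2_conditional`, `pseudo_r2`,
#'   `qq_correlation`.
#' @export
model_metrics <- function(fit) {
  var_fix <- stats::var(as.vector(fit$X %*% fit$coefficients))
  denom <- var_fix + fit$sigma2_b + fit$sigma2
  if (denom <= 0) stop("zero total variance")
  r2m <- var_fix / denom
  r2c <- (var_fix + fit$sigma2_b) / denom
  obs <- fit$y
  pr2 <- if (stats::sd(fit$fitted) == 0) 0 else stats::cor(obs, fit$fitted)^2
  res <- sort(fit$residuals)
  qth <- stats::qnorm(stats::ppoints(length(res)))
  list(r2_marginal = r2m, r2_conditional = r2c, pseudo_r2 = pr2,
       qq_correlation = stats::cor(res, qth))
}

#' Variance inflation factors
#'
#' For each fixed-effect predictor, VIF = 1 / (1 - R2) where R2 comes from
#' regressing that predictor on all the others (intercept included).
#' Perfectly collinear predictors yield infinite VIF.
#'
#' @param x an [lmm_ri()] fit, a model matrix, or a data.frame of
#'   predictors (non-intercept columns used).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  X <- if (inherits(x, "lmm_ri")) x$X else as.matrix(x)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 non-constant predictors")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' Likelihood-ratio test for the random intercept
#'
#' Compares the REML log-likelihood of the random-intercept model with
#' that of the fixed-effects-only model fitted to the identical rows
#' (the variance ratio pinned at zero), in the manner of lmerTest's
#' `ranova`. The statistic 2 * (logLik_mixed - logLik_fixed) is floored at
#' 0 and referred to the chi-square distribution with 1 degree of freedom.
#'
#' @param fit an [lmm_ri()] fit.
#' @return list with `statistic`, `df`, `p`, and both REML log-likelihoods.
#' @export
random_effect_lrt <- function(fit) {
  at0 <- reml_profile(0, fit$X, fit$y, fit$g)
  ll0 <- -0.5 * at0$neg2rl
  stat <- max(0, 2 * (fit$logLik_REML - ll0))
  list(statistic = stat, df = 1, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       logLik_mixed = fit$logLik_REML, logLik_fixed = ll0)
}
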