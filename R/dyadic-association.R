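# Covariate-adjusted cross-partner correlations and multivariable
# regression.  These are deliberately thin wrappers over least squares so
# every number is auditable against the normal equations.

new_effect_estimate <- function(beta, se, n, method, exposure = "exposure",
                                outcome = "outcome", p = NULL) {
  structure(list(beta = beta, se = se,
                 ci_low = beta - z975() * se, ci_high = beta + z975() * se,
                 p = p %||% norm_p(beta, se), n = n, method = method,
                 exposure = exposure, outcome = outcome),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate:%s> %s -> %s: beta=%.4g (se %.4g, 95%% CI %.4g, %.4g), p=%.3g, n=%d\n",
              x$method, x$exposure, x$outcome, x$beta, x$se, x$ci_low,
              x$ci_high, x$p, x$n))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(method = x$method, exposure = x$exposure, outcome = x$outcome,
             beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, p = x$p, n = x$n,
             stringsAsFactors = FALSE)
}

# Residualise y on [1, covmat] by least squares.
residualize <- function(y, covmat) {
  X <- cbind(`(Intercept)` = 1, covmat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_param("collinear covariate column(s): ",
               paste(dropped, collapse = ", "))
  }
  qr.resid(qr_x, y)
}

#' Covariate-adjusted Pearson correlation between partner traits
#'
#' Residualises both trait vectors on the covariates (with intercept) by
#' least squares and reports the Pearson correlation of the residuals.  The
#' confidence interval and p-value use the Fisher z transform with variance
#' `1 / (n - 3 - k)` where `k` is the number of covariate columns after
#' expansion, so the covariate degrees of freedom are charged to the
#' interval.  Each couple must contribute one orientation only (each
#' individual appears once).
#'
#' @param x index-partner trait vector.
#' @param y spouse trait vector (same couple order).
#' @param covariates optional covariate data.frame/matrix; factors are
#'   one-hot expanded dropping one level.
#' @param conf_level confidence level (default 0.95).
#' @param labels optional character pair naming the traits.
#' @return an object of class `correlation_result` with `r`, `n`,
#'   `ci_low`, `ci_high`, `p`, `k` and labels.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' adjusted_pearson(x, y)$r
adjusted_pearson <- function(x, y, covariates = NULL, conf_level = 0.95,
                             labels = c("trait_index", "trait_spouse")) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(as.data.frame(covariates))
    keep <- keep & cc
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  covmat <- covariate_matrix(covariates, n)
  k <- ncol(covmat)
  if (n < k + 4) stop_param("need at least covariates + 4 complete cases")
  rx <- residualize(x, covmat)
  ry <- residualize(y, covmat)
  tol <- 1e-12
  if (stats::sd(rx) <= tol * (1 + abs(mean(x))) ||
      stats::sd(ry) <= tol * (1 + abs(mean(y)))) {
    stop_param("zero residual variance")
  }
  r <- stats::cor(rx, ry)
  df_z <- n - 3 - k
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(df_z))
  p <- 2 * stats::pnorm(-abs(z) * sqrt(df_z))
  structure(list(r = r, n = n, ci_low = ci[1], ci_high = ci[2], p = p,
                 k = k, trait_index = labels[1], trait_spouse = labels[2]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: r=%.4f (95%% CI %.4f, %.4f), p=%.3g, n=%d\n",
              x$trait_index, x$trait_spouse, x$r, x$ci_low, x$ci_high, x$p,
              x$n))
  invisible(x)
}

#' @export
as.data.frame.correlation_result <- function(x, ...) {
  data.frame(trait_index = x$trait_index, trait_spouse = x$trait_spouse,
             r = x$r, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             n = x$n, stringsAsFactors = FALSE)
}

#' Multivariable regression of the spouse trait on the index trait
#'
#' Ordinary least squares of `outcome` on `exposure` plus covariates with
#' conventional standard errors.  When both traits are standardised the
#' slope approximates the covariate-partialled correlation, which is why
#' the phenotypic correlation and this regression can be read side by side.
#' Binary traits are left on the 0/1 scale so the slope is a risk
#' difference.
#'
#' @param outcome spouse trait vector.
#' @param exposure index trait vector.
#' @param covariates optional covariates as in [adjusted_pearson()].
#' @param labels optional character pair naming exposure and outcome.
#' @return an `effect_estimate` with method `"MV"`.
#' @export
mv_regression <- function(outcome, exposure, covariates = NULL,
                          labels = c("exposure", "outcome")) {
  keep <- !is.na(outcome) & !is.na(exposure)
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(as.data.frame(covariates))
    keep <- keep & cc
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  outcome <- outcome[keep]; exposure <- exposure[keep]
  n <- length(outcome)
  covmat <- covariate_matrix(covariates, n)
  if (stats::sd(exposure) == 0) stop_param("zero-variance exposure")
  X <- cbind(`(Intercept)` = 1, exposure = exposure, covmat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_param("rank-deficient design; collinear column(s): ",
               paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, outcome)
  res <- qr.resid(qr_x, outcome)
  sigma2 <- sum(res^2) / (n - ncol(X))
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv["exposure", "exposure"])
  new_effect_estimate(unname(coefs["exposure"]), se, n, "MV",
                      exposure = labels[1], outcome = labels[2])
}
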