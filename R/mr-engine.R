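# One-sample cross-partner Mendelian randomisation.
#
# The index individual's allele score instruments their own trait; the
# outcome is the partner's trait.  Because genotypes are fixed at
# conception and assigned independently of later shared environment, the
# two-stage estimate is protected from the shared-environment confounding
# that biases the multivariable regression.

#' Two-stage least squares with covariates
#'
#' Stage 1 regresses the exposure on the instrument(s) plus covariates;
#' stage 2 regresses the outcome on the fitted exposure plus covariates.
#' The standard error uses the instrumental-variable variance formula with
#' structural residuals (outcome minus `beta` times the *observed* exposure
#' minus covariate terms), not the naive OLS standard error of stage 2.
#' With `cluster` supplied, a couple-clustered sandwich variance is used
#' instead, respecting the dyadic duplication of the pooled analysis where
#' each person enters once as index and once as spouse.
#'
#' @param outcome spouse trait vector.
#' @param exposure index trait vector.
#' @param instrument numeric vector (e.g. an allele score) or matrix of
#'   instruments (e.g. per-variant dosages).
#' @param covariates optional covariates (exogenous; included in both
#'   stages).
#' @param cluster optional cluster id vector (couple id) for sandwich
#'   standard errors.
#' @param labels character pair naming exposure and outcome.
#' @return an `effect_estimate` with method `"2SLS"`; first-stage
#'   diagnostics (`partial_r2`, `f_stat`) and the structural residuals are
#'   attached as attributes `first_stage` and `residuals` (plus
#'   `instruments`/`covmat` for downstream over-identification tests).
#' @export
#' @examples
#' set.seed(1)
#' g <- rnorm(500); x <- 0.3 * g + rnorm(500); y <- 0.5 * x + rnorm(500)
#' two_stage_least_squares(y, x, g)$beta
two_stage_least_squares <- function(outcome, exposure, instrument,
                                    covariates = NULL, cluster = NULL,
                                    labels = c("exposure", "outcome")) {
  if (is.data.frame(instrument) && "score" %in% names(instrument)) {
    instrument <- instrument$score
  }
  Z_raw <- if (is.matrix(instrument)) instrument else
    matrix(instrument, ncol = 1, dimnames = list(NULL, "instrument"))
  keep <- !is.na(outcome) & !is.na(exposure) &
    stats::complete.cases(Z_raw)
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(as.data.frame(covariates))
    keep <- keep & cc
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  outcome <- outcome[keep]; exposure <- exposure[keep]
  Z_raw <- Z_raw[keep, , drop = FALSE]
  if (!is.null(cluster)) cluster <- cluster[keep]
  n <- length(outcome)
  covmat <- covariate_matrix(covariates, n)
  Z <- cbind(`(Intercept)` = 1, covmat, Z_raw)
  X <- cbind(`(Intercept)` = 1, covmat, exposure = exposure)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop_param("collinear instrument/covariate matrix")
  }
  # first-stage identification check on a single-index summary of Z
  fs <- instrument_strength(if (ncol(Z_raw) == 1L) Z_raw[, 1] else
    rowMeans(Z_raw), exposure, if (ncol(covmat)) covmat else NULL)
  if (!is.finite(fs$f_stat) || sqrt(fs$f_stat) < 1e-6) {
    stop_param("unidentified model: first-stage coefficient ",
               "indistinguishable from zero")
  }
  Xhat <- qr.fitted(qz, X)
  XtX <- crossprod(Xhat, X)            # X'P_Z X (= Xhat'Xhat)
  b <- solve(XtX, crossprod(Xhat, outcome))
  beta <- b["exposure", 1]
  u <- outcome - X %*% b               # structural residuals
  bread <- solve(XtX)
  if (is.null(cluster)) {
    sigma2 <- sum(u^2) / (n - ncol(X))
    vc <- sigma2 * bread
  } else {
    scores <- Xhat * as.numeric(u)
    g <- rowsum(scores, cluster)
    meat <- crossprod(g)
    G <- nrow(g)
    adj <- G / (G - 1) * (n - 1) / (n - ncol(X))
    vc <- adj * bread %*% meat %*% bread
  }
  se <- sqrt(vc["exposure", "exposure"])
  est <- new_effect_estimate(unname(beta), se, n, "2SLS",
                             exposure = labels[1], outcome = labels[2])
  attr(est, "first_stage") <- fs
  attr(est, "residuals") <- as.numeric(u)
  attr(est, "instruments") <- Z_raw
  attr(est, "covmat") <- covmat
  est
}

#' z-test for the difference between two effect estimates
#'
#' Compares, e.g., the multivariable-regression and two-stage estimates of
#' the same cross-partner effect:
#' \eqn{z = (\beta_1 - \beta_2) / \sqrt{se_1^2 + se_2^2}}, two-sided normal
#' p-value.  Agreement suggests the observational association is not driven
#' by shared-environment confounding.
#'
#' @param est1,est2 `effect_estimate` objects (or lists with `beta`, `se`)
#'   on the same exposure/outcome and scale.
#' @return list with `z` and `p`.
#' @export
#' @examples
#' mv_vs_mr_ztest(list(beta = -0.113, se = 0.005),
#'                list(beta = -0.152, se = 0.055))
mv_vs_mr_ztest <- function(est1, est2) {
  if (inherits(est1, "effect_estimate") && inherits(est2, "effect_estimate")) {
    if (!identical(est1$exposure, est2$exposure) ||
        !identical(est1$outcome, est2$outcome)) {
      stop_param("estimates are labelled with different exposure/outcome")
    }
  }
  z <- (est1$beta - est2$beta) / sqrt(est1$se^2 + est2$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sargan over-identification test
#'
#' With more instruments than exposures, the structural residuals should be
#' uncorrelated with every instrument.  The statistic is `n` times the
#' R-squared from regressing the two-stage structural residuals on the
#' instruments plus covariates, referred to chi-square with `J - 1` degrees
#' of freedom (single exposure).  With a single instrument the model is
#' just-identified and the test is returned as not applicable (`df = 0`,
#' `p = NA`) rather than as an error.
#'
#' @param fit an `effect_estimate` from [two_stage_least_squares()] with a
#'   multi-column instrument matrix (residuals/instruments are read from
#'   its attributes), or a numeric residual vector.
#' @param instruments instrument matrix (required when `fit` is a vector).
#' @param covariates optional covariates (read from `fit` when absent).
#' @return list with `stat`, `df`, `p`, `applicable`.
#' @export
sargan_test <- function(fit, instruments = NULL, covariates = NULL) {
  if (inherits(fit, "effect_estimate")) {
    u <- attr(fit, "residuals")
    instruments <- instruments %||% attr(fit, "instruments")
    covmat <- attr(fit, "covmat")
  } else {
    u <- as.numeric(fit)
    if (is.null(instruments)) stop_param("instruments matrix required")
    covmat <- covariate_matrix(covariates, length(u))
  }
  Z <- as.matrix(instruments)
  if (qr(Z)$rank < ncol(Z)) stop_param("collinear instrument columns")
  J <- ncol(Z)
  if (J < 2L) {
    return(list(stat = NA_real_, df = 0L, p = NA_real_, applicable = FALSE))
  }
  n <- length(u)
  X <- cbind(1, covmat, Z)
  res <- qr.resid(qr(X), u)
  r2 <- 1 - sum(res^2) / sum((u - mean(u))^2)
  stat <- n * r2
  df <- J - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), applicable = TRUE)
}

#' Per-variant Wald ratios for summary-statistic MR
#'
#' For each instrument variant, the exposure and the partner outcome are
#' regressed on the dosage (with covariates); the Wald ratio is
#' `beta_gy / beta_gx` with first-order standard error
#' `se_gy / |beta_gx|`, and the inverse-variance weight is `ratio_se^-2`.
#' Variants with `beta_gx` exactly zero are dropped with a log entry.
#'
#' @param genotypes `genotype_matrix` or dosage matrix restricted to the
#'   index individuals (couple order must match `exposure`/`outcome`).
#' @param exposure index trait vector.
#' @param outcome spouse trait vector.
#' @param covariates optional covariates.
#' @return data.frame of class `wald_ratio_set` with per-variant `beta_gx`,
#'   `se_gx`, `f_stat`, `beta_gy`, `se_gy`, `ratio`, `ratio_se`, `weight`;
#'   dropped variants are listed in the `dropped` attribute.
#' @export
per_snp_wald_ratios <- function(genotypes, exposure, outcome,
                                covariates = NULL) {
  dosage <- as_dosage_matrix(genotypes)
  keep <- !is.na(exposure) & !is.na(outcome)
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(as.data.frame(covariates))
    keep <- keep & cc
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  dosage <- dosage[keep, , drop = FALSE]
  exposure <- exposure[keep]; outcome <- outcome[keep]
  n <- length(exposure)
  covmat <- covariate_matrix(covariates, n)
  ids <- colnames(dosage) %||% paste0("variant", seq_len(ncol(dosage)))
  rows <- vector("list", ncol(dosage))
  dropped <- character(0)
  for (j in seq_len(ncol(dosage))) {
    d <- dosage[, j]
    ok <- !is.na(d)
    Xj <- cbind(1, dosage = d[ok], covmat[ok, , drop = FALSE])
    qx <- qr(Xj)
    fit_one <- function(y) {
      cf <- qr.coef(qx, y)
      r <- qr.resid(qx, y)
      s2 <- sum(r^2) / (sum(ok) - ncol(Xj))
      vmat <- solve(crossprod(Xj))
      c(beta = unname(cf[2]), se = sqrt(s2 * vmat[2, 2]))
    }
    gx <- fit_one(exposure[ok])
    gy <- fit_one(outcome[ok])
    if (gx[["beta"]] == 0) {
      dropped <- c(dropped, ids[j])
      next
    }
    rows[[j]] <- data.frame(
      variant_id = ids[j],
      beta_gx = gx[["beta"]], se_gx = gx[["se"]],
      f_stat = (gx[["beta"]] / gx[["se"]])^2,
      beta_gy = gy[["beta"]], se_gy = gy[["se"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop_param("no usable variants")
  out$ratio <- out$beta_gy / out$beta_gx
  out$ratio_se <- out$se_gy / abs(out$beta_gx)
  out$weight <- out$ratio_se^-2
  attr(out, "dropped") <- dropped
  class(out) <- c("wald_ratio_set", "data.frame")
  out
}

#' Construct a Wald-ratio set from summary statistics
#'
#' @param beta_gx,se_gx variant-exposure associations and SEs.
#' @param beta_gy,se_gy variant-outcome associations and SEs.
#' @param variant_id optional ids.
#' @return a `wald_ratio_set` data.frame.
#' @export
wald_ratio_set <- function(beta_gx, se_gx, beta_gy, se_gy,
                           variant_id = NULL) {
  if (any(beta_gx == 0)) stop_param("beta_gx must be nonzero")
  if (any(se_gx <= 0) || any(se_gy <= 0)) stop_param("SEs must be positive")
  out <- data.frame(
    variant_id = variant_id %||% paste0("variant", seq_along(beta_gx)),
    beta_gx = beta_gx, se_gx = se_gx,
    f_stat = (beta_gx / se_gx)^2,
    beta_gy = beta_gy, se_gy = se_gy,
    ratio = beta_gy / beta_gx, ratio_se = se_gy / abs(beta_gx),
    stringsAsFactors = FALSE)
  out$weight <- out$ratio_se^-2
  class(out) <- c("wald_ratio_set", "data.frame")
  out
}

#' Inverse-variance weighted estimate over Wald ratios
#'
#' Fixed-effect weighted mean of the per-variant ratios with weights
#' `ratio_se^-2`; `se = (sum w)^(-1/2)`.  With
#' `scale = "multiplicative"` the standard error is inflated by
#' `sqrt(max(1, Q/df))` to absorb over-dispersion.
#'
#' @param ratios a `wald_ratio_set`.
#' @param scale `"fixed"` (default) or `"multiplicative"`.
#' @param labels character pair naming exposure and outcome.
#' @return an `effect_estimate` with method `"IVW"`.
#' @export
ivw_estimate <- function(ratios, scale = c("fixed", "multiplicative"),
                         labels = c("exposure", "outcome")) {
  scale <- match.arg(scale)
  if (nrow(ratios) < 1L) stop_param("empty ratio set")
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (scale == "multiplicative" && nrow(ratios) > 1L) {
    Q <- sum(w * (ratios$ratio - beta)^2)
    se <- se * sqrt(max(1, Q / (nrow(ratios) - 1)))
  }
  new_effect_estimate(beta, se, nrow(ratios), "IVW",
                      exposure = labels[1], outcome = labels[2])
}

#' MR-Egger regression over Wald-ratio inputs
#'
#' Weighted least squares of `beta_gy` on `beta_gx` with an intercept,
#' weights `se_gy^-2`, after orienting every `beta_gx` non-negative
#' (flipping `beta_gy` along with it).  The slope is the pleiotropy-robust
#' effect estimate under the InSIDE assumption; an intercept distinguishable
#' from zero signals directional pleiotropy.  Standard errors come from the
#' weighted regression with t-distribution p-values (`df = J - 2`).
#'
#' @param ratios a `wald_ratio_set` with at least 3 variants.
#' @param labels character pair naming exposure and outcome.
#' @return list with `slope` and `intercept`, both `effect_estimate`s.
#' @export
egger_estimate <- function(ratios, labels = c("exposure", "outcome")) {
  if (nrow(ratios) < 3L) stop_param("MR-Egger needs at least 3 variants")
  s <- sign(ratios$beta_gx)
  gx <- ratios$beta_gx * s
  gy <- ratios$beta_gy * s
  w <- ratios$se_gy^-2
  fit <- stats::lm(gy ~ gx, weights = w)
  sm <- summary(fit)$coefficients
  df <- nrow(ratios) - 2L
  slope <- new_effect_estimate(sm["gx", 1], sm["gx", 2], nrow(ratios),
                               "Egger-slope", exposure = labels[1],
                               outcome = labels[2],
                               p = 2 * stats::pt(-abs(sm["gx", 3]), df))
  intercept <- new_effect_estimate(sm["(Intercept)", 1],
                                   sm["(Intercept)", 2], nrow(ratios),
                                   "Egger-intercept", exposure = labels[1],
                                   outcome = labels[2],
                                   p = 2 * stats::pt(-abs(sm["(Intercept)", 3]),
                                                     df))
  list(slope = slope, intercept = intercept)
}

# Weighted median of values v with positive weights w (lower weighted
# median: smallest v with cumulative weight >= half the total).
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cum <- cumsum(w)
  v[which(cum >= sum(w) / 2)[1]]
}

#' Least-absolute-deviation estimate over Wald ratios
#'
#' Minimises \eqn{\sum_i w_i |\beta_{gy,i} - b\, \beta_{gx,i}|} over the
#' scalar `b`, with weights `1/se_gy` (a through-origin weighted L1
#' regression, similar in spirit to the weighted-median estimator: the
#' solution is the weighted median of the per-variant ratios with weights
#' `|beta_gx| / se_gy`).  The standard error is a seeded bootstrap over
#' variants (the ratio set is the only input at this interface).
#'
#' @param ratios a `wald_ratio_set`.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed bootstrap seed.
#' @param labels character pair naming exposure and outcome.
#' @return an `effect_estimate` with method `"LAD"`.
#' @export
lad_estimate <- function(ratios, n_boot = 1000, seed = 1,
                         labels = c("exposure", "outcome")) {
  if (nrow(ratios) < 1L) stop_param("empty ratio set")
  est <- weighted_median(ratios$ratio, abs(ratios$beta_gx) / ratios$se_gy)
  boots <- with_seed(substream_seed(seed, "lad_bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(ratios), replace = TRUE)
      weighted_median(ratios$ratio[idx],
                      abs(ratios$beta_gx[idx]) / ratios$se_gy[idx])
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_effect_estimate(est, se, nrow(ratios), "LAD",
                      exposure = labels[1], outcome = labels[2])
}

#' Weak-instrument diagnostics for summary-statistic MR
#'
#' Reports the mean per-variant first-stage F statistic and the
#' heterogeneity-style I2 of the variant-exposure estimates
#' (`max(0, (Q - df)/Q) * 100` with inverse-variance weights on `beta_gx`),
#' an index of regression-dilution risk for MR-Egger inputs.
#'
#' @param ratios a `wald_ratio_set` including `se_gx`/`f_stat`.
#' @return list with `mean_f` and `i2_gx` (percent).
#' @export
weak_instrument_diagnostics <- function(ratios) {
  mean_f <- mean(ratios$f_stat)
  if (nrow(ratios) < 2L) return(list(mean_f = mean_f, i2_gx = 0))
  w <- ratios$se_gx^-2
  mu <- sum(w * ratios$beta_gx) / sum(w)
  Q <- sum(w * (ratios$beta_gx - mu)^2)
  df <- nrow(ratios) - 1L
  list(mean_f = mean_f, i2_gx = max(0, (Q - df) / Q) * 100)
}
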