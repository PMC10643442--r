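# Inverse-variance meta-analysis with heterogeneity statistics, used for
# sex-combination and effect-modification subgroup syntheses.

new_meta_result <- function(beta, se, Q, df, tau2 = 0, k = df + 1L,
                            model = "fixed") {
  i2 <- if (df > 0 && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  p_het <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  structure(list(beta = beta, se = se,
                 ci_low = beta - z975() * se, ci_high = beta + z975() * se,
                 p = norm_p(beta, se), Q = Q, df = df, i2 = i2,
                 p_het = p_het, tau2 = tau2, k = k, model = model),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result:%s> beta=%.4g (se %.4g), k=%d, Q=%.3g, I2=%.0f%%, P_het=%.3g%s\n",
              x$model, x$beta, x$se, x$k, x$Q, x$i2, x$p_het,
              if (x$model == "random") sprintf(", tau2=%.4g", x$tau2) else ""))
  invisible(x)
}

#' @export
as.data.frame.meta_result <- function(x, ...) {
  data.frame(model = x$model, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, p = x$p, k = x$k, Q = x$Q, df = x$df,
             i2 = x$i2, p_het = x$p_het, tau2 = x$tau2,
             stringsAsFactors = FALSE)
}

#' Recover a standard error from a printed confidence interval
#'
#' `se = (ci_high - ci_low) / (2 * z)`, with `z` the normal quantile for
#' the interval level; lets published subgroup intervals be re-used as
#' meta-analysis inputs.
#'
#' @param ci_low,ci_high interval bounds (`ci_high > ci_low`).
#' @param level interval level (default 0.95).
#' @return the implied standard error.
#' @export
#' @examples
#' ci_to_se(0.20, 1.60)
ci_to_se <- function(ci_low, ci_high, level = 0.95) {
  if (any(ci_high <= ci_low)) stop_param("ci_high must exceed ci_low")
  (ci_high - ci_low) / (2 * stats::qnorm(1 - (1 - level) / 2))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools estimates with weights `se^-2`; reports Cochran's Q, its
#' chi-square p-value (`df = k - 1`) and `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param betas vector of estimates (k >= 2).
#' @param ses vector of positive standard errors.
#' @return a `meta_result`.
#' @export
#' @examples
#' fixed_effect_meta(c(-0.02, 0.17, 0.22),
#'                   ci_to_se(c(-0.18, 0.05, 0.07), c(0.13, 0.39, 0.36)))
fixed_effect_meta <- function(betas, ses) {
  if (length(betas) < 2L) stop_param("need at least 2 estimates")
  if (length(betas) != length(ses)) stop_param("betas/ses length mismatch")
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop_param("standard errors must be positive")
  }
  w <- ses^-2
  beta <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta)^2)
  new_meta_result(beta, sqrt(1 / sum(w)), Q, length(betas) - 1L,
                  model = "fixed")
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-study variance as
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` from the
#' fixed-effect Q, then re-pools with weights `(se^2 + tau2)^-1`.  When
#' `Q <= df` the result coincides with the fixed-effect analysis.
#'
#' @inheritParams fixed_effect_meta
#' @return a `meta_result` with `tau2`.
#' @export
random_effects_meta <- function(betas, ses) {
  fe <- fixed_effect_meta(betas, ses)
  w <- ses^-2
  tau2 <- max(0, (fe$Q - fe$df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  beta <- sum(wr * betas) / sum(wr)
  new_meta_result(beta, sqrt(1 / sum(wr)), fe$Q, fe$df, tau2 = tau2,
                  model = "random")
}

# Tertile labels by linear-interpolation quantiles; ties go to the lower
# stratum (intervals closed on the right).
tertile_groups <- function(x) {
  qs <- stats::quantile(x, c(1, 2) / 3, na.rm = TRUE, type = 7)
  cut(x, breaks = c(-Inf, qs, Inf),
      labels = c("tertile1", "tertile2", "tertile3"), right = TRUE)
}

#' Subgroup MR scan with fixed-effect synthesis
#'
#' Splits the couples by an effect-modifier, re-runs the cross-partner
#' two-stage analysis within each subgroup and pools the subgroup estimates
#' with [fixed_effect_meta()]; heterogeneity (I2, P_het) across subgroups is
#' the effect-modification signal.
#'
#' @param data data.frame with one row per analysis pair, containing the
#'   exposure, outcome and instrument columns.
#' @param modifier vector (couple-level) defining subgroups: a factor /
#'   character vector used as-is, or a numeric vector split into tertiles.
#' @param exposure,outcome,instrument column names in `data`.
#' @param covariates optional covariate column names in `data`.
#' @param min_n subgroups smaller than this are dropped with a warning
#'   (default 50).
#' @return list with `subgroups` (label, beta, se, ci, p, n) and `meta`
#'   (a `meta_result`, or `NULL` with fewer than 2 usable subgroups).
#' @export
subgroup_scan <- function(data, modifier, exposure, outcome, instrument,
                          covariates = NULL, min_n = 50) {
  if (length(modifier) != nrow(data)) {
    stop_param("modifier must have one value per row of data")
  }
  groups <- if (is.numeric(modifier)) tertile_groups(modifier)
            else factor(modifier)
  labs <- levels(droplevels(groups))
  rows <- NULL
  for (g in labs) {
    idx <- which(groups == g)
    if (length(idx) < min_n) {
      warning("subgroup ", g, " has n=", length(idx), " < ", min_n,
              "; dropped")
      next
    }
    sub <- data[idx, , drop = FALSE]
    fit <- two_stage_least_squares(sub[[outcome]], sub[[exposure]],
                                   sub[[instrument]],
                                   if (!is.null(covariates))
                                     sub[covariates] else NULL,
                                   labels = c(exposure, outcome))
    rows <- rbind(rows, data.frame(subgroup = g, beta = fit$beta,
                                   se = fit$se, ci_low = fit$ci_low,
                                   ci_high = fit$ci_high, p = fit$p,
                                   n = fit$n, stringsAsFactors = FALSE))
  }
  meta <- if (!is.null(rows) && nrow(rows) >= 2L) {
    fixed_effect_meta(rows$beta, rows$se)
  } else NULL
  applicable <- !is.null(meta)
  if (!applicable && !is.null(rows) && nrow(rows) == 1L) {
    warning("single subgroup: meta-analysis not applicable")
  }
  list(subgroups = rows, meta = meta, applicable = applicable)
}
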