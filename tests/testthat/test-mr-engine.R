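# Two-stage least squares, z-test, Sargan, and summary-statistic
# estimators against independent oracles.

test_that("an identity instrument reproduces ordinary least squares", {
  set.seed(81)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  tsls <- two_stage_least_squares(y, x, x)
  ols <- mv_regression(y, x)
  expect_equal(tsls$beta, ols$beta, tolerance = 1e-10)
})

test_that("2SLS equals the ratio-of-covariances oracle after partialling", {
  # 12-row fixture with one covariate; oracle: partial the covariate out
  # of instrument, exposure and outcome, then beta = cov(z,y)/cov(z,x)
  z <- c(0, 1, 2, 1, 0, 2, 1, 0, 2, 2, 1, 0)
  x <- c(0.5, 1.1, 2.3, 0.9, -0.2, 2.8, 1.4, 0.3, 1.9, 2.2, 0.8, -0.4)
  y <- c(0.2, 0.9, 1.8, 0.4, 0.1, 2.1, 1.2, -0.3, 1.5, 1.7, 0.6, 0.0)
  cv <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  part <- function(v) resid(lm(v ~ cv))
  oracle <- cov(part(z), part(y)) / cov(part(z), part(x))
  fit <- two_stage_least_squares(y, x, z, data.frame(cv = cv))
  expect_equal(fit$beta, oracle, tolerance = 1e-10)
})

test_that("2SLS structural-residual SE differs from the naive stage-2 SE", {
  set.seed(82)
  n <- 2000
  z <- rnorm(n); u <- rnorm(n)
  x <- 0.5 * z + u + rnorm(n)
  y <- 0.3 * x + u + rnorm(n)
  fit <- two_stage_least_squares(y, x, z)
  # naive stage-2 OLS on the fitted exposure
  xhat <- fitted(lm(x ~ z))
  naive <- summary(lm(y ~ xhat))$coefficients["xhat", "Std. Error"]
  expect_gt(abs(fit$se - naive) / naive, 0.05)
  # and the IV variance formula reproduces the reported SE
  u_hat <- y - fit$beta * x - mean(y - fit$beta * x)
  sigma2 <- sum(u_hat^2) / (n - 2)
  se_oracle <- sqrt(sigma2 * solve(crossprod(cbind(1, xhat)))[2, 2])
  expect_equal(fit$se, se_oracle, tolerance = 1e-6)
})

test_that("an irrelevant instrument raises an identification error", {
  set.seed(83)
  x <- rnorm(200); y <- rnorm(200)
  z <- resid(lm(rnorm(200) ~ x))  # exactly orthogonal to the exposure
  expect_error(two_stage_least_squares(y, x, z),
               class = "dyadmr_parameter_error")
})

test_that("the MV-vs-MR z-test reproduces the published comparisons", {
  rows <- ukb_mv_mr_table()
  rows <- rows[rows$reproducible, ]
  for (i in seq_len(nrow(rows))) {
    p <- mv_vs_mr_ztest(list(beta = rows$mv_beta[i], se = rows$mv_se[i]),
                        list(beta = rows$mr_beta[i], se = rows$mr_se[i]))$p
    expect_equal(round(p, 3), rows$ztest_p[i],
                 info = rows$trait[i], tolerance = 1e-8)
  }
  ident <- mv_vs_mr_ztest(list(beta = 0.2, se = 0.1),
                          list(beta = 0.2, se = 0.3))
  expect_equal(ident$z, 0)
  expect_equal(ident$p, 1)
})

test_that("z-test refuses estimates with mismatched labels", {
  a <- mv_regression(rnorm(20), rnorm(20), labels = c("x", "y"))
  b <- mv_regression(rnorm(20), rnorm(20), labels = c("x", "z"))
  expect_error(mv_vs_mr_ztest(a, b), class = "dyadmr_parameter_error")
})

test_that("Sargan test matches the n.R2 oracle and degenerates gracefully", {
  set.seed(84)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.4 * z1 + 0.3 * z2 + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  fit <- two_stage_least_squares(y, x, cbind(z1 = z1, z2 = z2))
  sg <- sargan_test(fit)
  u <- attr(fit, "residuals")
  r2 <- summary(lm(u ~ z1 + z2))$r.squared
  expect_equal(sg$stat, n * r2, tolerance = 1e-8)
  expect_equal(sg$df, 1L)
  expect_equal(sg$p, pchisq(n * r2, 1, lower.tail = FALSE))

  single <- two_stage_least_squares(y, x, z1)
  sg1 <- sargan_test(single)
  expect_false(sg1$applicable)
  expect_equal(sg1$df, 0L)
  expect_true(is.na(sg1$p))

  expect_error(sargan_test(u, cbind(z1, z1)),
               class = "dyadmr_parameter_error")
})

test_that("per-variant ratios equal per-variant regression oracles", {
  co <- quick_cohort("interaction", n_couples = 800, beta_i = 0.25,
                     alpha_g = sqrt(0.2), n_snps = 6, seed = 85)
  w <- couples_wide(co)
  g <- attr(co, "genotypes")
  d <- g$dosage[match(w$female_id, rownames(g$dosage)), 1:6]
  ex <- standardize_traits(w$trait_female)
  out <- standardize_traits(w$trait_male)
  age <- w$age_female
  wr <- per_snp_wald_ratios(d, ex, out, data.frame(age = age))
  for (j in 1:6) {
    fx <- summary(lm(ex ~ d[, j] + age))$coefficients
    fy <- summary(lm(out ~ d[, j] + age))$coefficients
    expect_equal(wr$beta_gx[j], fx[2, 1], tolerance = 1e-10)
    expect_equal(wr$se_gx[j], fx[2, 2], tolerance = 1e-10)
    expect_equal(wr$beta_gy[j], fy[2, 1], tolerance = 1e-10)
    expect_equal(wr$ratio[j], fy[2, 1] / fx[2, 1], tolerance = 1e-10)
    expect_equal(wr$ratio_se[j], fy[2, 2] / abs(fx[2, 1]), tolerance = 1e-10)
  }
})

test_that("Wald-ratio arithmetic follows the first-order formulas", {
  wr <- wald_ratio_set(beta_gx = 0.5, se_gx = 0.05, beta_gy = 0.1,
                       se_gy = 0.05)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$ratio_se, 0.1)
  wr0 <- wald_ratio_set(0.5, 0.05, 0, 0.05)
  expect_equal(wr0$ratio, 0)
})

test_that("IVW is the inverse-variance weighted mean", {
  one <- wald_ratio_set(1, 0.1, 0.3, 0.1)
  est <- ivw_estimate(one)
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, 0.1)

  two <- wald_ratio_set(c(1, 1), c(0.1, 0.1), c(1, 0), c(1, 1))
  est2 <- ivw_estimate(two)
  expect_equal(est2$beta, 0.5)
  expect_equal(est2$se, 1 / sqrt(2))

  five <- make_ratio_fixture(5, b = 0.3, seed = 86)
  est5 <- ivw_estimate(five)
  w <- five$ratio_se^-2
  expect_equal(est5$beta, sum(w * five$ratio) / sum(w), tolerance = 1e-12)
  expect_equal(est5$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_error(ivw_estimate(five[0, ]), class = "dyadmr_parameter_error")
})

test_that("Egger regression matches the closed-form weighted fit", {
  # collinear-through-origin inputs: intercept 0, slope = common ratio
  gx <- c(0.2, 0.4, -0.3, 0.5)
  line <- wald_ratio_set(gx, rep(0.01, 4), 0.4 * gx, rep(0.05, 4))
  e <- egger_estimate(line)
  expect_lt(abs(e$intercept$beta), 1e-10)
  expect_equal(e$slope$beta, 0.4, tolerance = 1e-10)

  fix <- make_ratio_fixture(4, b = 0.25, seed = 87, pleiotropy = 0.02)
  e2 <- egger_estimate(fix)
  # closed-form weighted regression oracle on oriented inputs
  s <- sign(fix$beta_gx); gx <- fix$beta_gx * s; gy <- fix$beta_gy * s
  w <- fix$se_gy^-2
  xb <- sum(w * gx) / sum(w); yb <- sum(w * gy) / sum(w)
  slope <- sum(w * (gx - xb) * (gy - yb)) / sum(w * (gx - xb)^2)
  intercept <- yb - slope * xb
  expect_equal(e2$slope$beta, slope, tolerance = 1e-10)
  expect_equal(e2$intercept$beta, intercept, tolerance = 1e-10)

  expect_error(egger_estimate(make_ratio_fixture(2, seed = 88)),
               class = "dyadmr_parameter_error")
})

test_that("LAD solves the weighted L1 problem", {
  # symmetric odd set of equal-precision ratios: the median
  gx <- rep(1, 5)
  sym <- wald_ratio_set(gx, rep(0.01, 5), c(-0.2, 0.1, 0.3, 0.5, 0.8),
                        rep(0.1, 5))
  expect_equal(lad_estimate(sym, n_boot = 50)$beta, 0.3)

  # grid-search minimiser oracle
  fix <- make_ratio_fixture(9, b = 0.35, seed = 89)
  est <- lad_estimate(fix, n_boot = 50)$beta
  objective <- function(b) {
    sum(abs(fix$beta_gy - b * fix$beta_gx) / fix$se_gy)
  }
  grid <- seq(min(fix$ratio), max(fix$ratio), length.out = 200001)
  best <- grid[which.min(vapply(grid, objective, 0))]
  expect_equal(est, best, tolerance = 1e-6)
  expect_lte(objective(est), objective(best) + 1e-12)

  # degenerate: all ratios identical
  gx <- c(0.2, 0.5, 0.8)
  same <- wald_ratio_set(gx, rep(0.01, 3), 0.7 * gx, rep(0.05, 3))
  res <- lad_estimate(same, n_boot = 100)
  expect_equal(res$beta, 0.7, tolerance = 1e-12)
  expect_lt(res$se, 1e-10)
})

test_that("weak-instrument diagnostics follow the Q-based definition", {
  same <- wald_ratio_set(rep(0.3, 4), rep(0.05, 4), rnorm(4, 0, 0.01),
                         rep(0.05, 4))
  d <- weak_instrument_diagnostics(same)
  expect_equal(d$i2_gx, 0)
  expect_equal(d$mean_f, (0.3 / 0.05)^2)

  one <- wald_ratio_set(0.4, 0.1, 0.1, 0.1)
  expect_equal(weak_instrument_diagnostics(one)$mean_f, 16)

  fix <- make_ratio_fixture(6, seed = 90)
  d2 <- weak_instrument_diagnostics(fix)
  w <- fix$se_gx^-2
  mu <- sum(w * fix$beta_gx) / sum(w)
  Q <- sum(w * (fix$beta_gx - mu)^2)
  expect_equal(d2$i2_gx, max(0, (Q - 5) / Q) * 100, tolerance = 1e-12)
})

test_that("estimators agree on strong pleiotropy-free ratios", {
  fix <- make_ratio_fixture(25, b = 0.3, seed = 91)
  ivw <- ivw_estimate(fix)
  egg <- egger_estimate(fix)$slope
  lad <- lad_estimate(fix, n_boot = 300, seed = 91)
  expect_lt(abs(ivw$beta - egg$beta), 2 * sqrt(ivw$se^2 + egg$se^2))
  expect_lt(abs(ivw$beta - lad$beta), 2 * sqrt(ivw$se^2 + lad$se^2))
  # single instrument: IVW equals the Wald ratio
  one <- fix[1, ]
  class(one) <- class(fix)
  expect_equal(ivw_estimate(one)$beta, one$ratio)
})

test_that("GRS-instrumented 2SLS matches the GRS-level Wald ratio", {
  co <- quick_cohort("interaction", n_couples = 3000, beta_i = 0.2,
                     alpha_g = sqrt(0.1), n_snps = 10, seed = 92)
  w <- couples_wide(co)
  ex <- standardize_traits(w$trait_female)
  out <- standardize_traits(w$trait_male)
  grs <- w$grs_trait_female
  tsls <- two_stage_least_squares(out, ex, grs)
  bx <- coef(lm(ex ~ grs))[2]
  by <- coef(lm(out ~ grs))[2]
  expect_equal(tsls$beta, unname(by / bx), tolerance = 1e-10)
})

test_that("couple-clustered SEs respond to duplicated orientations", {
  co <- quick_cohort("interaction", n_couples = 1500, beta_i = 0.2,
                     alpha_g = sqrt(0.1), n_snps = 10, seed = 93)
  w <- couples_wide(co)
  # pooled two-orientation data: each couple contributes both directions
  out <- standardize_traits(c(w$trait_male, w$trait_female))
  ex <- standardize_traits(c(w$trait_female, w$trait_male))
  grs <- c(w$grs_trait_female, w$grs_trait_male)
  cl <- c(w$couple_id, w$couple_id)
  plain <- two_stage_least_squares(out, ex, grs)
  clustered <- two_stage_least_squares(out, ex, grs, cluster = cl)
  expect_equal(plain$beta, clustered$beta, tolerance = 1e-10)
  expect_gt(clustered$se, 0)
  expect_false(isTRUE(all.equal(plain$se, clustered$se)))
})
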