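# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no stored data.

# Summary-level Wald-ratio fixture: strong instruments, true slope `b`,
# optional directional pleiotropy added to beta_gy.
make_ratio_fixture <- function(n = 10, b = 0.3, seed = 42, se_gy = 0.05,
                               pleiotropy = 0) {
  set.seed(seed)
  beta_gx <- runif(n, 0.2, 0.6) * sample(c(-1, 1), n, replace = TRUE)
  se_gx <- rep(0.01, n)
  beta_gy <- b * beta_gx + pleiotropy + rnorm(n, 0, se_gy / 4)
  wald_ratio_set(beta_gx, se_gx, beta_gy, rep(se_gy, n))
}

# Wide couple table for a quick scenario run.
quick_cohort <- function(scenario = "interaction", n_couples = 2000,
                         alpha_g = sqrt(0.1), beta_i = 0, rho_a = 0,
                         c_share = 0, n_snps = 20, seed = 1) {
  params <- scenario_params(scenario, n_couples = n_couples,
                            alpha_g = alpha_g, beta_i = beta_i,
                            rho_a = rho_a, c_share = c_share,
                            n_snps = n_snps, seed = seed)
  simulate_couples(params)
}

# Manual OLS coefficient/SE oracle from the normal equations.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(sigma2 * solve(XtX))))
}
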