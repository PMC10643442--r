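# Unweighted score construction, orientation bookkeeping, instrument
# strength, cross-partner score correlation.

make_instruments <- function(g, beta = NULL, pval = NULL) {
  v <- g$variants
  data.frame(variant_id = v$variant_id, effect_allele = v$effect_allele,
             other_allele = v$other_allele,
             beta = beta %||% rep(0.1, nrow(v)),
             pval = pval %||% rep(1e-9, nrow(v)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scores count trait-increasing alleles with orientation flips", {
  g <- simulate_genotypes(4, 3, maf = 0.4, seed = 61)
  g$dosage[1, ] <- c(2L, 2L, 2L)
  g$dosage[2, ] <- c(2L, 0L, 1L)
  ins <- make_instruments(g)
  grs <- build_unweighted_grs(g, ins)
  expect_equal(grs$score[1], 6)           # homozygous increasing at all 3
  expect_equal(grs$score[2], 3)
  expect_equal(grs$n_snps_used[1], 3)

  # negative GWAS beta flips the contribution: dosage 2 contributes 0
  ins$beta[1] <- -0.1
  grs <- build_unweighted_grs(g, ins)
  expect_equal(grs$score[1], (2 - 2) + 2 + 2)

  # swapped allele order in the genotype file flips the dosage
  ins$beta[1] <- 0.1
  ins$effect_allele[1] <- g$variants$other_allele[1]
  ins$other_allele[1] <- g$variants$effect_allele[1]
  grs <- build_unweighted_grs(g, ins)
  expect_equal(grs$score[1], 0 + 2 + 2)
})

test_that("scores equal a per-cell summation oracle on a 20-row fixture", {
  g <- simulate_genotypes(20, 8, maf = 0.3, seed = 62, missing_rate = 0.05)
  ins <- make_instruments(g, beta = c(0.2, -0.3, 0.1, -0.05, 0.4, 0.2,
                                      -0.1, 0.3))
  grs <- build_unweighted_grs(g, ins)
  # brute-force oracle: orient each cell, mean-impute per variant
  oriented <- g$dosage
  for (j in seq_len(8)) {
    if (ins$beta[j] < 0) oriented[, j] <- 2 - oriented[, j]
    mu <- mean(oriented[, j], na.rm = TRUE)
    oriented[is.na(oriented[, j]), j] <- mu
  }
  expect_equal(grs$score, unname(rowSums(oriented)))
})

test_that("allele and variant mismatches are reported", {
  g <- simulate_genotypes(5, 3, maf = 0.3, seed = 63)
  ins <- make_instruments(g)
  ins$effect_allele[2] <- "T"; ins$other_allele[2] <- "T"
  expect_error(build_unweighted_grs(g, ins), ins$variant_id[2],
               class = "dyadmr_parameter_error")
  ins <- make_instruments(g)
  ins$variant_id[3] <- "rs999999"
  expect_error(build_unweighted_grs(g, ins), "rs999999",
               class = "dyadmr_parameter_error")
  grs <- build_unweighted_grs(g, ins, allow_missing_variants = TRUE)
  expect_equal(grs$n_snps_used[1], 2)
  expect_equal(attr(grs, "dropped"), "rs999999")
})

test_that("relabelling alleles together with the sign leaves scores fixed", {
  g <- simulate_genotypes(30, 6, maf = 0.25, seed = 64)
  ins <- make_instruments(g, beta = runif(6, -0.5, 0.5))
  base <- build_unweighted_grs(g, ins)$score
  flipped <- ins
  flipped$effect_allele <- ins$other_allele
  flipped$other_allele <- ins$effect_allele
  flipped$beta <- -ins$beta
  expect_equal(build_unweighted_grs(g, flipped)$score, base)
})

test_that("palindromic and duplicate instruments raise warnings", {
  g <- simulate_genotypes(5, 2, maf = 0.3, seed = 65)
  g$variants$effect_allele <- c("A", "C")
  g$variants$other_allele <- c("T", "G")
  ins <- make_instruments(g)
  expect_warning(build_unweighted_grs(g, ins), "palindromic")
  ins2 <- rbind(ins, ins[1, ])
  expect_warning(expect_warning(build_unweighted_grs(g, ins2), "duplicate"),
                 "palindromic")
})

test_that("instrument strength equals the two-regression oracle", {
  set.seed(66)
  n <- 300
  score <- rnorm(n)
  covs <- data.frame(age = rnorm(n))
  trait <- 0.3 * score + 0.2 * covs$age + rnorm(n)
  diag <- instrument_strength(score, trait, covs)
  full <- lm(trait ~ score + age, data = cbind(covs, score, trait))
  reduced <- lm(trait ~ age, data = cbind(covs, trait))
  rssf <- sum(resid(full)^2); rssr <- sum(resid(reduced)^2)
  expect_equal(diag$partial_r2, (rssr - rssf) / rssr, tolerance = 1e-10)
  tstat <- summary(full)$coefficients["score", "t value"]
  expect_equal(diag$f_stat, tstat^2, tolerance = 1e-10)
})

test_that("null instruments rarely clear the weak-instrument bar", {
  # alpha_g = 0: F ~ F(1, n); P(F > 10) is tiny, so F < 10 nearly always
  set.seed(67)
  below <- vapply(1:200, function(i) {
    g <- simulate_genotypes(5000, 5, maf = 0.3, seed = 670 + i)
    score <- rowSums(g$dosage)
    trait <- rnorm(5000)
    instrument_strength(score, trait)$f_stat < 10
  }, TRUE)
  expect_gte(mean(below), 0.95)
})

test_that("tier relaxation never shrinks the instrument count", {
  g <- simulate_genotypes(200, 10, maf = 0.3, seed = 68)
  ins <- make_instruments(g, pval = c(1e-9, 1e-9, 1e-8, 4e-8, 1e-7, 4e-7,
                                      1e-6, 4e-6, 1e-5, 4e-5))
  pairs <- data.frame(index_id = rownames(g$dosage)[1:100],
                      spouse_id = rownames(g$dosage)[101:200])
  res <- grs_spousal_correlation(ins, g, pairs)
  expect_equal(res$n_snps, c(4, 6, 8, 10))
  expect_true(all(diff(res$n_snps) >= 0))
})

test_that("score correlation separates assortment from interaction", {
  rho <- 0.5; r2 <- 0.2
  wa <- couples_wide(quick_cohort("assortment", n_couples = 20000,
                                  rho_a = rho, alpha_g = sqrt(r2),
                                  seed = 70))
  ra <- adjusted_pearson(wa$grs_trait_female, wa$grs_trait_male)
  expect_gt(ra$r, 0)
  expect_lt(abs(ra$r - rho * r2), 4 / sqrt(20000))

  wi <- couples_wide(quick_cohort("interaction", n_couples = 20000,
                                  beta_i = 0.2, alpha_g = sqrt(r2),
                                  seed = 71))
  ri <- adjusted_pearson(wi$grs_trait_female, wi$grs_trait_male)
  expect_lt(abs(ri$r), 3 / sqrt(20000))

  # identical score vectors correlate perfectly
  expect_equal(adjusted_pearson(wa$grs_trait_female,
                                wa$grs_trait_female)$r, 1)
})
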