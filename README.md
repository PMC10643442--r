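# dyadmr

Dyadic Mendelian randomisation for spousal trait concordance.

Couples resemble each other for many behavioural traits — sleep among
them.  A phenotypic correlation between partners is, on its own,
uninformative about mechanism: it can reflect **assortative mating**
(similar people pair up), **partner interaction** (partners influence each
other after pairing) or **shared-environment confounding**.  `dyadmr`
implements the genetic toolkit that separates these:

* a cross-partner causal effect is estimated by one-sample Mendelian
  randomisation: the index partner's unweighted genetic risk score
  \(G\) instruments their own trait \(X\), and the outcome is the
  partner's trait \(Y\), via two-stage least squares
  \(\hat\beta_{2SLS} = \operatorname{cov}(G, Y)/\operatorname{cov}(G, X)\)
  (with covariates partialled out).  Genotypes are fixed at conception,
  so this estimate is immune to shared-environment confounding;
* a cross-partner **risk-score correlation** can only pre-date the
  partnership, so it diagnoses assortative mating;
* comparing the multivariable-regression and 2SLS estimates with a
  z-test, \(z = (\beta_{MV} - \beta_{2SLS})/\sqrt{se_{MV}^2 +
  se_{2SLS}^2}\), quantifies how much of the observational association
  survives the genetic design.

The package covers the full pipeline: a synthetic couple-cohort simulator
with the three generative scenarios built in; spouse-pair reconstruction
from household descriptors; parent-pair reconstruction from
identity-by-descent sharing with Mendelian-concordance checking;
questionnaire and accelerometer sleep-trait encoders; covariate-adjusted
cross-partner correlations (Fisher-z intervals); instrument-strength
diagnostics (partial R², first-stage F); sensitivity estimators (IVW,
MR-Egger, weighted-L1/LAD, Sargan over-identification); and
inverse-variance meta-analysis with Cochran's Q, I² and P_het for
sex-combination and effect-modification analyses.

## Worked example

Simulate a partner-interaction cohort at the calibrated survey scale
(47,050 couples, risk score explaining 0.6% of trait variance, true
partner effect 0.13 SD per SD), then estimate the effect three ways:

```r
library(dyadmr)

params <- scenario_preset("ukb-like", seed = 1)
cohort <- simulate_couples(params)
w      <- couples_wide(cohort)

x <- standardize_traits(w$trait_female)   # index partner's trait
y <- standardize_traits(w$trait_male)     # spouse's trait

adjusted_pearson(x, y)
#> <correlation_result> trait_index ~ trait_spouse: r=0.2589
#>   (95% CI 0.2504, 0.2673), p=0, n=47050

mv <- mv_regression(y, x)
mr <- two_stage_least_squares(y, x, w$grs_trait_female)
mr
#> <effect_estimate:2SLS> exposure -> outcome: beta=0.04939 (se 0.05863,
#>   95% CI -0.06552, 0.1643), p=0.4, n=47050

mv_vs_mr_ztest(mv, mr)$p
#> [1] 0.0003672708
```

Reading the output: the phenotypic correlation (~0.26) matches the
analytic value 2·0.13/(1 + 0.13²) implied by the reciprocal-interaction
model; the single-draw 2SLS estimate (0.049, SE 0.059) is consistent with
the generating 0.13 — at a 0.6% variance fraction one replicate is noisy,
and across 100 replicates the mean estimate is 0.136 with 95% interval
coverage (see the acceptance output below).  The score correlation
diagnostic separates the scenarios:

```r
adjusted_pearson(w$grs_trait_female, w$grs_trait_male)$r
#> [1] 3.571596e-05   # interaction: no score correlation
```

whereas an assortment scenario (`rho_a = 0.5`, score variance fraction
0.2) gives a score correlation near the analytic 0.5 × 0.2 = 0.1.

Published summary numbers can be re-analysed directly; for example the
heterogeneity of the sleep-duration partner effect across age tertiles,
from the printed subgroup intervals:

```r
ex <- ukb_subgroup_examples()$sleep_duration_age
fixed_effect_meta(ex$beta, ci_to_se(ex$ci_low, ex$ci_high))
#> <meta_result:fixed> beta=0.1253 (se 0.04586), k=3, Q=5.28, I2=62%,
#>   P_het=0.0714
```

## Package layout

* `R/synthetic-genotypes.R`, `R/synthetic-cohort.R`,
  `R/synthetic-household.R` — generative models
* `R/pair-inference.R` — spouse pairs, trios, Mendelian concordance
* `R/phenotype-codec.R` — trait encoders, accelerometer QC, conventions
* `R/dyadic-association.R`, `R/grs.R`, `R/mr-engine.R`,
  `R/meta-tools.R` — estimators
* `R/pipeline.R` + `inst/cli/dyadmr.R` — orchestration and CLI
* `vignettes/dyadic-mr-methods.Rmd` — models, assumptions, design choices
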