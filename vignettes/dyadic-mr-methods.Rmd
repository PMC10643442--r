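---
title: "Dyadic Mendelian randomisation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic Mendelian randomisation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmr)
```

## The scientific question

Couples resemble each other for many traits, including sleep behaviour.
Within a couple, concordance for a trait such as sleep duration can arise
from three distinct processes:

1. **Assortative mating** — people pair with phenotypically similar
   partners, so the similarity pre-dates the partnership;
2. **Partner interaction** — partners influence each other's behaviour
   after pairing, so traits converge over time;
3. **Shared-environment confounding** — the household exposes both
   partners to common causes.

These processes have different interventional implications (only partner
interaction means changing one partner's sleep changes the other's), but
they produce identical phenotypic correlations.  Genotypes break the tie.
An individual's genotype is fixed at conception and assigned independently
of the later shared household, so:

* a **cross-partner causal effect** estimated by instrumenting the index
  partner's trait with their own genotype is immune to shared-environment
  confounding;
* a **cross-partner genotype (risk-score) correlation** can only arise if
  sorting happened before pairing, i.e. from assortment.

The resulting signature matrix drives everything in this package:

| process | phenotypic r | genetic cross-partner effect | score correlation |
|---|---|---|---|
| interaction | > 0 | > 0 | about 0 |
| assortment | > 0 | > 0 | > 0 |
| confounding | > 0 | about 0 | about 0 |

## The generative model behind the simulator

`simulate_couples()` draws, per individual, a standardised latent
liability

$$X^{*} = \alpha_g G + C + e,$$

with $G$ the standardised unweighted allele score,
$C \sim N(0, c_{share})$ a couple-shared environmental factor and
$e \sim N(0, 1 - \alpha_g^2 - c_{share})$ independent noise, so that
$\operatorname{Var}(X^{*}) = 1$ and the score explains $\alpha_g^2$ of the
liability variance.  Genotypes are unlinked Hardy-Weinberg variants
(`simulate_genotypes()`); linkage disequilibrium is deliberately absent
because instrument lists in real analyses are pre-pruned.

**Partner interaction** is modelled reciprocally as a simultaneous system

$$X_f = X_f^{*} + \beta_i X_m, \qquad X_m = X_m^{*} + \beta_i X_f,$$

solved exactly: $(X_f, X_m)^\top = (I - \beta_i J)^{-1}(X_f^*, X_m^*)^\top$
with $J$ the swap matrix, which requires $|\beta_i| < 1$.  The implied
cross-partner correlation is $2\beta_i / (1 + \beta_i^2)$, and the
structural effect recovered by two-stage least squares is exactly
$\beta_i$.  We default to reciprocal influence because nothing in the
dyadic data identifies the direction; a one-directional variant is a
special case ($\beta$ applied to one equation only) that users can emulate
by post-processing the latent components.

**Assortment** is implemented as Gaussian-copula rank matching: partners'
liabilities are converted to normal scores, a noisy target
$t = \rho_a z_f + \sqrt{1-\rho_a^2}\,\varepsilon$ is formed, and males are
matched to females by the ranks of $t$.  No mate-choice mechanism is
specified by the substantive literature; rank matching is the minimal
mechanism that achieves a target matching correlation $\rho_a$ without
distorting marginals.  Under joint normality it implies a cross-partner
score correlation of $\rho_a \alpha_g^2$, which the tests verify by
simulation.

**Confounding** adds the shared $C$ to both partners after pairing, giving
a cross-partner correlation of exactly $c_{share}$ and, by construction,
no genotype-outcome link across partners.

**Observed traits.** Ordinal questionnaire traits are produced by
thresholding the standardised liability at the Gaussian quantiles of
configured category probabilities (the bundled `ukb_trait_panel()` uses
marginals typical of a large middle-aged UK couple cohort: e.g. 53.6% of
men and 30.2% of women with partner-reported snoring, mean L5 midpoint
27.3 h = 3:18 am); continuous traits are affine maps of the liability.
Thresholding attenuates correlations relative to the latent scale, which
is realistic for coarse questionnaire scales.

**What the simulator does not emulate:** linkage disequilibrium,
age-dependent trait trajectories, relationship dissolution, missing-data
mechanisms correlated with phenotype, and population structure.  Passing
tests therefore show that the estimators are correct under the stated
generative model, not that real-data biases of those kinds are absent.

**Calibration preset.** `scenario_preset("ukb-like")` fixes 47,050
couples, a score variance fraction of 0.006 ($\alpha_g = \sqrt{0.006}$)
and $\beta_i = 0.13$, mirroring the scale at which published spousal
sleep-duration analyses operate (scores explaining 0.1-1.4% of trait
variance, cross-partner effects around 0.13 SD per SD).  The confounding
and assortment test magnitudes ($c_{share} = 0.3$, $\rho_a = 0.5$ with
$\alpha_g^2 = 0.2$) are free parameters — no published generative values
exist — chosen once so each diagnostic's expected signal sits well above
Monte-Carlo noise at the simulated sample sizes.

## Pair and trio reconstruction

`derive_spouse_pairs()` implements the household-matching rules: both
members report living with a spouse, match exactly on years at address,
occupants, vehicles, accommodation type, rental status, 1-km grid
coordinates and recruitment centre, and are genotyped.  Exclusions:
groups of more than two sharing identical descriptors, same-sex pairs,
pairs reporting identical paternal *and* maternal ages at death (all four
values non-missing — a sibling signature), and pairs with relatedness
above 0.1.  Matching is exact equality after the 1-km quantisation; no
tolerance is applied because none is defined for these categorical and
quantised fields.  An individual matching candidates in two "different"
households cannot arise under exact-equality grouping — identical fields
place all candidates in one group, where the more-than-two rule discards
them; this is the conservative resolution of ambiguous matches.  Every
rejected candidate is tagged in the exclusion log.

`identify_trios()` reconstructs parent pairs from IBD sharing: candidate
parents share at least 42.5% of the genome IBD1 and at most 10% IBD2 with
the index individual, and the two parents share at most 20% IBD1 with each
other (this removes sibling pairs, IBD1 about 50%, and parent-child
impostors).  `mendelian_concordance_check()` then tests transmission
consistency at 100 random common (MAF > 0.3), well-called variants,
accepting trios concordant at 95 or more; the concordance predicate is an
exhaustive enumeration of one-allele-per-parent transmissions, tested
against a brute-force oracle.

## Trait encoding conventions

* Chronotype is a 5-level ordinal with "Do not know" mapped to the
  intermediate category 3 (it is excluded from the derived
  evening-vs-morning binary); "Prefer not to say" is always missing.
* Insomnia frequency is 3-level; the derived binary contrasts "usually"
  against never/sometimes.
* Snoring stays on the 0/1 scale throughout, so regression output reads
  as a risk difference.
* The 23andMe-style dialect is binary morning-vs-night ("It depends",
  "I'm not sure" and "Neither" missing — "Neither" belongs to no level of
  the binary), insomnia diagnosis, self-reported snoring, and integer
  sleep hours with responses below 3 h or above 12 h removed.
* Accelerometer QC first removes device-flagged records, then applies the
  Q3 + 1.5 IQR fence per recording-error variable, computed over the
  flag-clean records (the ordering is a documented choice; computing the
  fence after flag removal keeps corrupted recordings from inflating the
  fence).  Quartiles use the linear-interpolation convention
  (`quantile(type = 7)`).
* L5/M10 timings live on a linear 12-36 hours-from-previous-midnight
  axis and are never wrapped, so cross-person arithmetic stays linear;
  `l5_to_clock()` renders a value for reporting (27.3 becomes 3:18 am).
* `standardize_traits()` uses the sample SD (n-1); ordinal traits are
  analysed as equally spaced integers so slopes read as SD per SD.

## Estimators and numerical choices

**Adjusted correlation.** Both trait vectors are residualised on the
covariates by least squares and the Pearson correlation of residuals is
reported.  The Fisher-z interval uses variance $1/(n - 3 - k)$, charging
the $k$ covariate columns to the degrees of freedom; at tens of thousands
of couples the correction is negligible but it is the honest count.
Categorical covariates are one-hot expanded dropping one level;
complete-case analysis per trait pair, no imputation.

**Two-stage least squares.** Stage 1 regresses the exposure on
instrument(s) plus covariates, stage 2 the outcome on the fitted exposure
plus covariates.  The variance uses structural residuals
$y - \hat\beta x_{observed} - \text{covariate terms}$ — not the naive
stage-2 residuals — with denominator $n - p$.  A couple-clustered
sandwich variance is available for pooled two-orientation analyses in
which every individual appears once as index and once as partner; the
default conventional SE reproduces the usual single-orientation analysis.
A first-stage coefficient with $|t| < 10^{-6}$ raises an identification
error rather than returning an exploding ratio.

**Over-identification.** The Sargan statistic is $n R^2$ from regressing
the structural residuals on instruments plus covariates (centred $R^2$),
with $J - 1$ degrees of freedom; a just-identified model returns a
flagged not-applicable result instead of an error.

**Summary-statistic estimators.** Per-variant associations are computed
by covariate-adjusted regressions; ratios use the first-order SE
$se_{gy}/|\beta_{gx}|$.  IVW is the fixed-effect weighted mean (a
multiplicative over-dispersion scaling is available by flag).  MR-Egger
orients all $\beta_{gx} \ge 0$, fits weighted least squares with weights
$se_{gy}^{-2}$, and reports t-based p-values on $J - 2$ degrees of
freedom.  The LAD estimator minimises
$\sum_i |\beta_{gy,i} - b\,\beta_{gx,i}|/se_{gy,i}$, solved exactly as the
weighted median of ratios with weights $|\beta_{gx,i}|/se_{gy,i}$ (the
lower weighted median is taken on ties; a grid-search oracle confirms the
minimiser to 1e-6).  Its SE is a seeded bootstrap over variants: the
ratio set is the only input at this interface, so resampling couples is
not possible here — a deliberate interface choice, documented rather than
hidden.  Weak-instrument diagnostics report the mean per-variant F and
the Q-based I2 of the $\beta_{gx}$, the regression-dilution index for
Egger inputs.

**Meta-analysis.** Fixed-effect pooling with $se^{-2}$ weights, Cochran's
Q, $I^2 = \max(0,(Q - df)/Q) \times 100$ and its chi-square p-value;
random effects use DerSimonian-Laird $\tau^2$.  `ci_to_se()` recovers a
standard error from a printed interval width; published subgroup
intervals are occasionally asymmetric around their point estimate (a
rounding artefact), and using the width regardless reproduces the
published heterogeneity statistics.  Subgroup tertiles use
linear-interpolation quantiles with ties assigned to the lower stratum.

**Score construction.** Unweighted scores count trait-increasing alleles:
dosages are oriented to the instrument's effect allele (flipping when the
genotype file stores the pair in the opposite order) and flipped again
when the reported GWAS effect is negative.  Unweighted scores avoid
importing Winner's-curse-inflated discovery weights.  Sporadically
missing dosages are mean-imputed per variant to preserve sample size;
palindromic variants are accepted with a warning (no frequency-based
strand inference); duplicate ids warn because lists are assumed
pre-pruned for LD.

## Problem sizes used in the tests

The test-suite simulations are sized so each property is decided by
Monte-Carlo margins, not luck: scenario-signature checks use 20,000
couples with thresholds at 3-4 times the null standard error
$1/\sqrt{n}$; the confounding type-I study uses 500 replicates of 2,000
couples (binomial tolerance $\pm 3\sqrt{0.05 \cdot 0.95 / 500} \approx
0.029$); effect recovery uses 200 replicates of the full 47,050-couple
preset and requires the mean estimate within two Monte-Carlo standard
errors of the generating 0.13 and interval coverage near 95%.  The
acceptance script repeats the recovery study at 100 replicates.

## Known limitations

* The simulator's covariates (age, centre, chip, principal components)
  are noise by construction; they exercise the adjustment code paths but
  cannot create the population-structure confounding they are meant to
  absorb in real data.
* One-sample MR with per-variant instruments is weak-instrument-prone;
  the Egger slope in particular is biased when the I2 of the
  variant-exposure estimates is low.  The diagnostics report this but do
  not correct it (no SIMEX).
* Assortment and interaction are identified through the score
  correlation, which has power only when the score explains a
  non-trivial variance fraction; at 0.6% variance explained, realistic
  assortment produces score correlations near the detection floor — the
  same limitation the substantive literature reports.
* The household matcher assumes canonicalised inputs; it applies no fuzzy
  matching, and quantisation error in coordinates is assumed to be
  resolved upstream.
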