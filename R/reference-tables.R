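# Published summary tables used as worked-example inputs.  These are
# printed numbers from a large UK couple cohort (rounded to the precision
# at which they were reported); they are inputs to the worked examples, not
# outputs of this package.

#' Published spousal MV-vs-MR comparison table
#'
#' Multivariable-regression and two-stage-least-squares estimates (SD per
#' SD; risk difference for snoring) with standard errors for nine sleep
#' traits in ~47,000 couples, as printed.  The `ztest_p` column holds the
#' printed p-value of the z-test for the MV-2SLS difference; all rows
#' except ease of waking reproduce from the rounded inputs via
#' [mv_vs_mr_ztest()].
#'
#' @return data.frame with one row per trait.
#' @export
ukb_mv_mr_table <- function() {
  data.frame(
    trait = c("chronotype", "ease_of_waking", "sleep_duration", "insomnia",
              "snoring", "acc_l5_timing", "acc_sleep_duration",
              "acc_sleep_episodes", "acc_sleep_efficiency"),
    n_pairs = c(47235, 47325, 47050, 47369, 45546, 3454, 3454, 3454, 3454),
    mv_beta = c(-0.113, 0.015, 0.111, 0.005, -0.008, 0.241, 0.108, 0.069,
                0.075),
    mv_se = c(0.005, 0.005, 0.005, 0.005, 0.004, 0.016, 0.016, 0.016,
              0.016),
    mr_beta = c(-0.152, -0.039, 0.131, -0.046, -0.154, 0.486, 0.132,
                -0.267, 0.024),
    mr_se = c(0.055, 0.079, 0.048, 0.054, 0.061, 0.232, 0.131, 0.247,
              0.138),
    ztest_p = c(0.480, 0.503, 0.679, 0.347, 0.017, 0.292, 0.856, 0.175,
                0.714),
    reproducible = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Published snoring counts among male and female spouses
#'
#' Partner-reported snoring counts: 53.6% of male spouses
#' (24,411 / 45,546) versus 30.2% of female spouses (13,761 / 45,546).
#'
#' @return data.frame with `sex`, `yes`, `no`, `n`.
#' @export
ukb_snoring_counts <- function() {
  data.frame(sex = c("female", "male"),
             yes = c(13761, 24411), no = c(31785, 21135),
             n = c(45546, 45546), stringsAsFactors = FALSE)
}

#' Published effect-modification subgroup estimates
#'
#' Printed subgroup estimates (with 95% CIs) for two worked examples:
#' the sleep-duration cross-partner effect by thirds of mean couple age,
#' and the L5-timing effect by presence of children in the household.
#'
#' @return named list of data.frames (`sleep_duration_age`, `l5_children`)
#'   with `subgroup`, `beta`, `ci_low`, `ci_high`.
#' @export
ukb_subgroup_examples <- function() {
  list(
    sleep_duration_age = data.frame(
      subgroup = c("40-54y", "55-61y", "62-70y"),
      beta = c(-0.02, 0.17, 0.22),
      ci_low = c(-0.18, 0.05, 0.07),
      ci_high = c(0.13, 0.39, 0.36), stringsAsFactors = FALSE),
    l5_children = data.frame(
      subgroup = c("no_children", "children"),
      beta = c(0.90, -0.11),
      ci_low = c(0.20, -0.82),
      ci_high = c(1.60, 0.62), stringsAsFactors = FALSE)
  )
}
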