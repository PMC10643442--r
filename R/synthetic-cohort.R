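#' Scenario parameters for the couple-cohort simulator
#'
#' Bundles the structural parameters of the dyadic generative model.  On a
#' standardised latent scale, each individual's trait liability is
#' \deqn{X^* = \alpha_g G + C + e,}
#' where `G` is the standardised unweighted allele score, `C` a couple-shared
#' environmental factor with variance `c_share`, and `e` independent noise
#' with variance `1 - alpha_g^2 - c_share`.  Scenarios then add:
#'
#' * **assortment** — partners are paired by Gaussian-copula rank matching on
#'   the liability so that the cross-partner liability correlation is
#'   approximately `rho_a`;
#' * **interaction** — reciprocal partner influence
#'   \eqn{X_f = X_f^* + \beta_i X_m}, \eqn{X_m = X_m^* + \beta_i X_f},
#'   solved exactly as a simultaneous system (requires `|beta_i| < 1`);
#' * **confounding** — `c_share > 0` only;
#' * **mixed** — any combination of the above;
#' * **null** — all three parameters zero.
#'
#' @param scenario one of `"null"`, `"assortment"`, `"interaction"`,
#'   `"confounding"`, `"mixed"`.
#' @param n_couples number of couples.
#' @param alpha_g effect of the standardised score on the own liability
#'   (SD per score SD); the score explains `alpha_g^2` of the liability
#'   variance, so a realistic 0.6% corresponds to `alpha_g = sqrt(0.006)`.
#' @param rho_a target cross-partner matching correlation under assortment.
#' @param beta_i partner-interaction structural effect (SD per SD),
#'   `|beta_i| < 1`.
#' @param c_share shared-confounder variance fraction in `[0, 1)`.
#' @param n_snps instrument variants per trait.
#' @param maf MAF specification passed to [simulate_genotypes()].
#' @param traits trait panel: a list of trait specifications as returned by
#'   [ukb_trait_panel()], or the default single standardised continuous
#'   trait.
#' @param seed master integer seed.
#' @return an object of class `scenario_params`.
#' @seealso [scenario_preset()] for the calibrated `"ukb-like"` preset.
#' @export
scenario_params <- function(scenario = c("null", "assortment", "interaction",
                                         "confounding", "mixed"),
                            n_couples = 1000,
                            alpha_g = sqrt(0.006),
                            rho_a = 0,
                            beta_i = 0,
                            c_share = 0,
                            n_snps = 70,
                            maf = c(0.05, 0.5),
                            traits = NULL,
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (n_couples < 1) stop_param("n_couples must be >= 1")
  if (abs(beta_i) >= 1) {
    stop_param("|beta_i| must be < 1 (the simultaneous system is otherwise ",
               "non-invertible)")
  }
  if (abs(rho_a) > 1) stop_param("rho_a must lie in [-1, 1]")
  if (c_share < 0 || c_share >= 1) stop_param("c_share must lie in [0, 1)")
  if (alpha_g^2 + c_share > 1) {
    stop_param("variance fractions alpha_g^2 + c_share exceed 1")
  }
  # Scenario tags zero out the parameters they do not use.
  if (scenario == "null") rho_a <- beta_i <- c_share <- 0
  if (scenario == "assortment") beta_i <- c_share <- 0
  if (scenario == "interaction") rho_a <- c_share <- 0
  if (scenario == "confounding") rho_a <- beta_i <- 0
  traits <- traits %||% list(list(name = "trait", type = "continuous",
                                  female = list(mean = 0, sd = 1),
                                  male = list(mean = 0, sd = 1)))
  structure(list(scenario = scenario, n_couples = as.integer(n_couples),
                 alpha_g = alpha_g, rho_a = rho_a, beta_i = beta_i,
                 c_share = c_share, n_snps = as.integer(n_snps), maf = maf,
                 traits = traits, seed = as.integer(seed)),
            class = "scenario_params")
}

#' Calibrated scenario presets
#'
#' `"ukb-like"` mirrors the scale of a large genotyped couple cohort:
#' 47,050 couples, an allele score explaining 0.6% of trait variance, and a
#' partner-interaction effect of 0.13 SD per SD — the magnitudes reported
#' for spousal sleep duration.
#'
#' @param name preset name; currently `"ukb-like"`.
#' @param scenario scenario tag (default `"interaction"`).
#' @param seed master seed.
#' @param ... overrides forwarded to [scenario_params()].
#' @return a `scenario_params` object.
#' @export
scenario_preset <- function(name = "ukb-like", scenario = "interaction",
                            seed = 1, ...) {
  if (name != "ukb-like") stop_param("unknown preset: ", name)
  args <- list(scenario = scenario, n_couples = 47050,
               alpha_g = sqrt(0.006), beta_i = 0.13, n_snps = 70, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_params, args)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params> ", x$scenario, ": ", x$n_couples, " couples, ",
      "alpha_g=", signif(x$alpha_g, 3), ", rho_a=", x$rho_a,
      ", beta_i=", x$beta_i, ", c_share=", x$c_share,
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Sleep-trait panel with realistic marginals
#'
#' Returns the trait specifications used to give simulated couples
#' questionnaire-like marginal distributions: five self-report traits
#' (5-level chronotype, 4-level ease of waking, sleep duration in hours,
#' 3-level insomnia frequency, binary snoring) and four accelerometer traits
#' (L5 timing on the hours-from-previous-midnight axis, sleep duration,
#' nocturnal sleep episodes, sleep efficiency), with sex-specific category
#' probabilities and moments matching a large UK cohort of middle-aged
#' couples (e.g. 53.6% of men vs 30.2% of women with partner-reported
#' snoring, L5 midpoint 27.3 h = 3:18 am).
#'
#' Ordinal traits are generated by thresholding the standardised latent
#' liability at the Gaussian quantiles of the cumulative category
#' probabilities; continuous traits are affine maps of the liability.
#'
#' @return a list of trait specifications for [scenario_params()].
#' @export
ukb_trait_panel <- function() {
  list(
    list(name = "chronotype", type = "ordinal",
         female = list(probs = c(0.064, 0.262, 0.084, 0.352, 0.239)),
         male = list(probs = c(0.070, 0.246, 0.128, 0.329, 0.226))),
    list(name = "ease_of_waking", type = "ordinal",
         female = list(probs = c(0.042, 0.157, 0.527, 0.274)),
         male = list(probs = c(0.019, 0.093, 0.486, 0.402))),
    list(name = "sleep_duration", type = "continuous",
         female = list(mean = 7.3, sd = 1.1),
         male = list(mean = 7.2, sd = 1.0)),
    list(name = "insomnia", type = "ordinal",
         female = list(probs = c(0.175, 0.503, 0.322)),
         male = list(probs = c(0.304, 0.460, 0.236))),
    list(name = "snoring", type = "binary",
         female = list(prob = 0.302), male = list(prob = 0.536)),
    list(name = "acc_l5_timing", type = "continuous",
         female = list(mean = 27.3, sd = 1.0),
         male = list(mean = 27.3, sd = 1.0)),
    list(name = "acc_sleep_duration", type = "continuous",
         female = list(mean = 7.5, sd = 0.8),
         male = list(mean = 7.3, sd = 0.9)),
    list(name = "acc_sleep_episodes", type = "continuous",
         female = list(mean = 16.9, sd = 3.5),
         male = list(mean = 17.6, sd = 3.8)),
    list(name = "acc_sleep_efficiency", type = "continuous",
         female = list(mean = 0.78, sd = 0.06),
         male = list(mean = 0.75, sd = 0.07))
  )
}

# Map a standardised latent vector to the observed trait scale.
latent_to_observed <- function(latent, spec_sex) {
  if (!is.null(spec_sex$probs)) {               # ordinal
    cuts <- stats::qnorm(utils::head(cumsum(spec_sex$probs), -1L))
    # standardise latent first so category frequencies hit the targets
    z <- (latent - mean(latent)) / stats::sd(latent)
    as.integer(findInterval(z, cuts) + 1L)
  } else if (!is.null(spec_sex$prob)) {         # binary
    z <- (latent - mean(latent)) / stats::sd(latent)
    as.integer(z > stats::qnorm(1 - spec_sex$prob))
  } else {                                      # continuous
    spec_sex$mean + spec_sex$sd * latent
  }
}

#' Simulate a couple cohort under a generative scenario
#'
#' Generates `2 * n_couples` individuals with genotypes, per-trait allele
#' scores and phenotypes under the structural model of [scenario_params()],
#' then pairs them into couples.  Under assortment, pairing is by
#' Gaussian-copula rank matching on the (first) trait liability with match
#' noise calibrated so the cross-partner liability correlation is
#' approximately `rho_a`; otherwise pairing is random.  Partner interaction
#' is applied after pairing by solving the reciprocal-influence system
#' exactly; a couple-shared confounder is added to both partners before the
#' interaction step.
#'
#' Each trait uses its own block of `n_snps` variants, so scores for
#' different traits are independent.
#'
#' @param params a [scenario_params()] object.
#' @param genotypes optional `genotype_matrix` with at least
#'   `2 * n_couples` rows and `n_snps * length(traits)` variants; simulated
#'   from `params` when `NULL`.
#' @return a `couple_cohort` data.frame, one row per individual, with
#'   `individual_id`, `couple_id`, `sex`, covariates (`age`, `centre`,
#'   `chip`, `PC1`..`PC10`), per-trait standardised score (`grs_<trait>`),
#'   observed trait values, and the latent couple confounder.  The genotypes
#'   and parameters are attached as attributes `genotypes` and `params`.
#' @export
#' @examples
#' cohort <- simulate_couples(scenario_params("interaction", n_couples = 200,
#'                                            beta_i = 0.2, seed = 7))
#' head(cohort[, c("individual_id", "couple_id", "sex", "trait")])
simulate_couples <- function(params, genotypes = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  nc <- params$n_couples
  n <- 2L * nc
  traits <- params$traits
  m_total <- params$n_snps * length(traits)
  if (is.null(genotypes)) {
    genotypes <- simulate_genotypes(n, m_total, maf = params$maf,
                                    seed = substream_seed(params$seed,
                                                          "cohort_genotypes"))
  }
  dosage <- as_dosage_matrix(genotypes)
  if (nrow(dosage) < n) stop_param("genotype count must be >= 2 * n_couples")
  if (ncol(dosage) < m_total) {
    stop_param("need ", m_total, " variants (", params$n_snps, " per trait)")
  }

  with_seed(substream_seed(params$seed, "simulate_couples"), {
    sigma_e <- sqrt(max(0, 1 - params$alpha_g^2 - params$c_share))

    # Per-trait standardised scores and baseline liabilities (independent
    # across traits apart from nothing; shared structure enters per couple).
    grs <- liab <- matrix(0, n, length(traits))
    for (t in seq_along(traits)) {
      cols <- ((t - 1L) * params$n_snps + 1L):(t * params$n_snps)
      raw <- rowSums(dosage[seq_len(n), cols, drop = FALSE])
      grs[, t] <- (raw - mean(raw)) / stats::sd(raw)
      liab[, t] <- params$alpha_g * grs[, t] + sigma_e * stats::rnorm(n)
    }

    # --- pairing ---------------------------------------------------------
    females <- seq_len(nc)
    males <- nc + seq_len(nc)
    if (params$scenario %in% c("assortment", "mixed") && params$rho_a != 0) {
      rho <- params$rho_a
      zf <- stats::qnorm(rank(liab[females, 1]) / (nc + 1))
      zm <- stats::qnorm(rank(liab[males, 1]) / (nc + 1))
      target <- rho * zf + sqrt(1 - rho^2) * stats::rnorm(nc)
      # female ranked r on the target gets the male ranked r on liability
      males <- males[order(zm)][rank(target, ties.method = "first")]
    } else {
      males <- males[sample.int(nc)]
    }

    # --- couple-shared confounder and reciprocal interaction -------------
    conf <- sqrt(params$c_share) * stats::rnorm(nc)
    b <- params$beta_i
    xf <- liab[females, , drop = FALSE] + conf
    xm <- liab[males, , drop = FALSE] + conf
    if (b != 0) {
      det <- 1 - b^2
      xf_new <- (xf + b * xm) / det
      xm_new <- (xm + b * xf) / det
      xf <- xf_new; xm <- xm_new
    }

    # --- covariates ------------------------------------------------------
    couple_age <- stats::rnorm(nc, 57.6, 6.5)
    age_f <- couple_age - 0.85 + stats::rnorm(nc, 0, 3)
    age_m <- couple_age + 0.85 + stats::rnorm(nc, 0, 3)
    centre <- sprintf("centre%02d", sample.int(22, nc, replace = TRUE))
    chip <- sample(c("axiom", "bileve"), n, replace = TRUE,
                   prob = c(0.9, 0.1))
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))

    ids <- rownames(dosage)[seq_len(n)]
    ord <- c(females, males) # row i: female of couple i; row nc+i: male
    out <- data.frame(
      individual_id = ids[ord],
      couple_id = sprintf("couple%05d", c(seq_len(nc), seq_len(nc))),
      sex = rep(c("female", "male"), each = nc),
      age = c(age_f, age_m),
      centre = rep(centre, 2L),
      chip = chip,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(pcs))
    for (t in seq_along(traits)) {
      tn <- traits[[t]]$name
      out[[paste0("grs_", tn)]] <- c(grs[females, t], grs[males, t])
      lat <- c(xf[, t], xm[, t])
      obs <- numeric(n)
      f_idx <- seq_len(nc); m_idx <- nc + seq_len(nc)
      obs[f_idx] <- latent_to_observed(lat[f_idx], traits[[t]]$female)
      obs[m_idx] <- latent_to_observed(lat[m_idx], traits[[t]]$male)
      out[[tn]] <- obs
    }
    out$confounder <- rep(conf, 2L)
    attr(out, "params") <- params
    attr(out, "genotypes") <- genotypes
    class(out) <- c("couple_cohort", "data.frame")
    out
  })
}

#' Reshape a couple cohort to one row per couple
#'
#' @param cohort a `couple_cohort`.
#' @param traits trait names to spread; defaults to all traits in the
#'   attached parameters.
#' @return a data.frame with one row per couple and `<trait>_female` /
#'   `<trait>_male` (plus `grs_` and `age_` analogues) columns.
#' @export
couples_wide <- function(cohort, traits = NULL) {
  params <- attr(cohort, "params")
  traits <- traits %||% vapply(params$traits, `[[`, "", "name")
  f <- cohort[cohort$sex == "female", , drop = FALSE]
  m <- cohort[cohort$sex == "male", , drop = FALSE]
  m <- m[match(f$couple_id, m$couple_id), , drop = FALSE]
  out <- data.frame(couple_id = f$couple_id,
                    female_id = f$individual_id, male_id = m$individual_id,
                    age_female = f$age, age_male = m$age,
                    centre = f$centre, stringsAsFactors = FALSE)
  for (tn in traits) {
    out[[paste0(tn, "_female")]] <- f[[tn]]
    out[[paste0(tn, "_male")]] <- m[[tn]]
    gn <- paste0("grs_", tn)
    if (gn %in% names(f)) {
      out[[paste0(gn, "_female")]] <- f[[gn]]
      out[[paste0(gn, "_male")]] <- m[[gn]]
    }
  }
  out
}
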