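# Configuration-driven orchestration: simulate -> pair -> correlate -> MR
# -> GRS correlation -> subgroups, with a run manifest and TSV outputs.

#' Build or load a pipeline configuration
#'
#' A configuration is a plain list (YAML-serialisable) with fields:
#' `seed`, `scenario` (preset arguments for [scenario_params()]), `stages`
#' (logical toggles: `correlations`, `mr`, `grs_correlation`, `subgroups`),
#' and optional `out_dir`.  All randomness flows from the single `seed`.
#'
#' @param x a list, or path to a YAML file.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    seed = 1,
    scenario = list(scenario = "interaction", n_couples = 2000,
                    alpha_g = sqrt(0.006), beta_i = 0.13, rho_a = 0,
                    c_share = 0, n_snps = 70),
    stages = list(correlations = TRUE, mr = TRUE, grs_correlation = TRUE,
                  subgroups = FALSE),
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, x)
  cfg$stages <- utils::modifyList(defaults$stages, cfg$stages %||% list())
  structure(cfg, class = c("pipeline_config", "list"))
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the dyadic analysis pipeline on a simulated cohort
#'
#' Executes the enabled stages in dependency order: cohort simulation,
#' spouse-pair recovery from the simulated household table, per-trait
#' standardisation, cross-partner correlations, MV + two-stage MR with the
#' MV-vs-MR z-test, cross-partner score correlation by p-value tier, and an
#' optional subgroup scan.  Row counts, the seed and package version are
#' recorded in the manifest; with `out_dir` set, each result family is
#' written as TSV.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @return invisibly, a list with `cohort`, `pairs`, `correlations`, `mr`,
#'   `grs_correlation`, `subgroups` and `manifest`.
#' @export
#' @examples
#' bundle <- run_pipeline(pipeline_config(list(
#'   seed = 7, scenario = list(n_couples = 300),
#'   stages = list(grs_correlation = FALSE))))
#' bundle$mr
run_pipeline <- function(config = pipeline_config()) {
  config <- pipeline_config(unclass(config))
  manifest <- list(package_version = as.character(utils::packageVersion("dyadmr")),
                   seed = config$seed, stages = config$stages, counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  # --- simulate --------------------------------------------------------
  scen <- config$scenario
  scen$seed <- NULL
  params <- stage("simulate", do.call(scenario_params,
                                      c(scen, list(seed = config$seed))))
  cohort <- stage("simulate", simulate_couples(params))
  manifest$counts$individuals <- nrow(cohort)
  hh <- stage("simulate", simulate_household_table(
    cohort, seed = substream_seed(config$seed, "pipeline_household")))

  # --- pair ------------------------------------------------------------
  paired <- stage("pair", derive_spouse_pairs(hh$households, hh$ibd))
  manifest$counts$pairs <- nrow(paired$pairs)
  manifest$counts$pair_exclusions <- nrow(paired$exclusions)

  traits <- vapply(params$traits, `[[`, "", "name")
  wide <- couples_wide(cohort)
  # restrict to recovered pairs (recovery is exact for decoy-free tables)
  wide <- wide[wide$female_id %in% paired$pairs$female_id, , drop = FALSE]

  results <- list(cohort = cohort, pairs = paired, manifest = manifest)

  # --- correlations ----------------------------------------------------
  if (isTRUE(config$stages$correlations)) {
    rows <- NULL
    for (tn in traits) {
      xf <- standardize_traits(wide[[paste0(tn, "_female")]])
      xm <- standardize_traits(wide[[paste0(tn, "_male")]])
      res <- adjusted_pearson(xf, xm,
                              covariates = wide[c("age_female", "age_male",
                                                  "centre")],
                              labels = c(tn, tn))
      rows <- rbind(rows, as.data.frame(res))
    }
    results$correlations <- rows
    write_stage_tsv(rows, config$out_dir, "correlations")
  }

  # --- MR --------------------------------------------------------------
  if (isTRUE(config$stages$mr)) {
    rows <- NULL
    for (tn in traits) {
      exb <- standardize_traits(wide[[paste0(tn, "_female")]])
      out <- standardize_traits(wide[[paste0(tn, "_male")]])
      grs <- wide[[paste0("grs_", tn, "_female")]]
      covs <- wide[c("age_female", "age_male", "centre")]
      mv <- mv_regression(out, exb, covs, labels = c(tn, tn))
      mr <- two_stage_least_squares(out, exb, grs, covs,
                                    labels = c(tn, tn))
      zt <- mv_vs_mr_ztest(mv, mr)
      rows <- rbind(rows, data.frame(
        trait = tn, n_pairs = mv$n,
        mv_beta = mv$beta, mv_se = mv$se, mv_ci_low = mv$ci_low,
        mv_ci_high = mv$ci_high, mv_p = mv$p,
        mr_beta = mr$beta, mr_se = mr$se, mr_ci_low = mr$ci_low,
        mr_ci_high = mr$ci_high, mr_p = mr$p,
        ztest_p = zt$p, stringsAsFactors = FALSE))
    }
    results$mr <- rows
    write_stage_tsv(rows, config$out_dir, "mr")
  }

  # --- GRS correlation -------------------------------------------------
  if (isTRUE(config$stages$grs_correlation)) {
    rows <- NULL
    for (tn in traits) {
      res <- adjusted_pearson(wide[[paste0("grs_", tn, "_female")]],
                              wide[[paste0("grs_", tn, "_male")]],
                              covariates = wide[c("age_female", "age_male",
                                                  "centre")],
                              labels = c(paste0("grs_", tn),
                                         paste0("grs_", tn)))
      rows <- rbind(rows, as.data.frame(res))
    }
    results$grs_correlation <- rows
    write_stage_tsv(rows, config$out_dir, "grs_correlation")
  }

  # --- subgroups -------------------------------------------------------
  if (isTRUE(config$stages$subgroups)) {
    tn <- traits[1]
    dat <- data.frame(
      exposure = standardize_traits(wide[[paste0(tn, "_female")]]),
      outcome = standardize_traits(wide[[paste0(tn, "_male")]]),
      instrument = wide[[paste0("grs_", tn, "_female")]])
    modifier <- (wide$age_female + wide$age_male) / 2
    sc <- subgroup_scan(dat, modifier, "exposure", "outcome", "instrument")
    results$subgroups <- sc
    if (!is.null(sc$subgroups)) {
      write_stage_tsv(sc$subgroups, config$out_dir, "subgroups")
    }
  }

  for (nm in c("correlations", "mr", "grs_correlation")) {
    if (!is.null(results[[nm]])) {
      manifest$counts[[nm]] <- nrow(results[[nm]])
    } else {
      manifest$counts[[nm]] <- "skipped"
    }
  }
  results$manifest <- manifest
  if (!is.null(config$out_dir)) {
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  invisible(results)
}
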