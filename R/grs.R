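# Unweighted genetic risk scores and instrument diagnostics.

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Build unweighted trait-increasing allele scores
#'
#' The score is the total count of trait-increasing alleles over the
#' instrument variants: each dosage is oriented to the instrument's effect
#' allele (flipped to `2 - d` when the genotype file stores the allele pair
#' in the opposite order) and flipped again when the reported GWAS effect is
#' negative, so every contribution counts trait-increasing alleles.
#' Unweighted scores avoid importing overestimated discovery-sample weights
#' (Winner's curse).
#'
#' Sporadically missing dosages are mean-imputed from the variant's
#' observed oriented mean so the score keeps its sample size.  Palindromic
#' variants (A/T, C/G) are accepted as-is with a warning; duplicate
#' instrument ids raise a warning (input lists are assumed pre-pruned).
#'
#' @param genotypes a `genotype_matrix`.
#' @param instruments data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta` (GWAS effect per effect allele), optional `se`,
#'   `pval`.
#' @param allow_missing_variants drop instruments absent from the genotype
#'   data (logged in the `dropped` attribute) instead of erroring.
#' @return data.frame (`individual_id`, `score`, `n_snps_used`) of class
#'   `grs_vector`; per-variant orientation flags are in the `orientation`
#'   attribute.
#' @export
build_unweighted_grs <- function(genotypes, instruments,
                                 allow_missing_variants = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  require_columns(instruments,
                  c("variant_id", "effect_allele", "other_allele", "beta"),
                  "instruments")
  if (anyDuplicated(instruments$variant_id)) {
    warning("duplicate instrument variant id(s): ",
            paste(unique(instruments$variant_id[
              duplicated(instruments$variant_id)]), collapse = ", "))
  }
  vmeta <- genotypes$variants
  idx <- match(instruments$variant_id, vmeta$variant_id)
  missing <- instruments$variant_id[is.na(idx)]
  if (length(missing)) {
    if (!allow_missing_variants) {
      stop_param("instrument variant(s) absent from genotypes: ",
                 paste(missing, collapse = ", "),
                 " (set allow_missing_variants = TRUE to drop)")
    }
    instruments <- instruments[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  pal <- paste(instruments$effect_allele, instruments$other_allele,
               sep = "/") %in% PALINDROMIC
  if (any(pal)) {
    warning("palindromic instrument variant(s) accepted as-is: ",
            paste(instruments$variant_id[pal], collapse = ", "))
  }
  same <- instruments$effect_allele == vmeta$effect_allele[idx] &
    instruments$other_allele == vmeta$other_allele[idx]
  swapped <- instruments$effect_allele == vmeta$other_allele[idx] &
    instruments$other_allele == vmeta$effect_allele[idx]
  bad <- !(same | swapped)
  if (any(bad)) {
    stop_param("allele mismatch (neither order) for variant(s): ",
               paste(instruments$variant_id[bad], collapse = ", "))
  }
  dosage <- genotypes$dosage[, idx, drop = FALSE]
  flip_strand <- swapped
  flip_sign <- instruments$beta < 0
  flip <- xor(flip_strand, flip_sign)
  oriented <- dosage
  oriented[, flip] <- 2 - oriented[, flip, drop = FALSE]
  # mean-impute missing dosages from the observed oriented mean
  if (anyNA(oriented)) {
    mu <- colMeans(oriented, na.rm = TRUE)
    for (j in which(colSums(is.na(oriented)) > 0)) {
      oriented[is.na(oriented[, j]), j] <- mu[j]
    }
  }
  out <- data.frame(individual_id = rownames(genotypes$dosage),
                    score = rowSums(oriented),
                    n_snps_used = nrow(instruments),
                    stringsAsFactors = FALSE)
  attr(out, "orientation") <- data.frame(
    variant_id = instruments$variant_id,
    strand_flipped = flip_strand, sign_flipped = flip_sign,
    palindromic = pal, stringsAsFactors = FALSE)
  if (length(missing)) attr(out, "dropped") <- missing
  class(out) <- c("grs_vector", "data.frame")
  out
}

#' First-stage instrument-strength diagnostics
#'
#' Regresses the trait on the score plus covariates and reports the partial
#' R-squared of the score, `(RSS_reduced - RSS_full) / RSS_reduced`, and the
#' first-stage F statistic (the squared t statistic of the score
#' coefficient).  F below ~10 is the conventional weak-instrument flag.
#'
#' @param grs a `grs_vector` or numeric score vector.
#' @param trait trait vector (same individual order).
#' @param covariates optional covariates.
#' @return list of class `instrument_diagnostics` with `partial_r2`,
#'   `f_stat`, `n`, `k`.
#' @export
instrument_strength <- function(grs, trait, covariates = NULL) {
  score <- if (is.data.frame(grs)) grs$score else grs
  keep <- !is.na(score) & !is.na(trait)
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(as.data.frame(covariates))
    keep <- keep & cc
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  score <- score[keep]; trait <- trait[keep]
  n <- length(score)
  covmat <- covariate_matrix(covariates, n)
  if (n < ncol(covmat) + 3) stop_param("need at least covariates + 3 cases")
  fit <- mv_regression(trait, score, covariates)
  rss_full <- function(X) sum(qr.resid(qr(X), trait)^2)
  full <- rss_full(cbind(1, score, covmat))
  reduced <- rss_full(cbind(1, covmat))
  structure(list(partial_r2 = (reduced - full) / reduced,
                 f_stat = (fit$beta / fit$se)^2, n = n, k = ncol(covmat)),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("<instrument_diagnostics> partial R2=%.4g, F=%.4g, n=%d\n",
              x$partial_r2, x$f_stat, x$n))
  invisible(x)
}

#' Cross-partner score correlation by p-value tier
#'
#' The assortative-mating diagnostic: genotypes are fixed at conception, so
#' any cross-partner correlation of the allele scores must pre-date the
#' partnership.  For each p-value tier the instrument list is restricted to
#' `pval < tier`, scores are rebuilt for both partners and the
#' covariate-adjusted correlation is computed with [adjusted_pearson()]
#' (one orientation per couple).
#'
#' @param instruments instrument data.frame including a `pval` column.
#' @param genotypes a `genotype_matrix` covering both partners.
#' @param pairs data.frame with `index_id` and `spouse_id` columns.
#' @param covariates optional per-couple covariates.
#' @param tiers p-value thresholds (default `5e-8, 5e-7, 5e-6, 5e-5`).
#' @return data.frame with one row per tier: `tier`, `n_snps`, `r`,
#'   `ci_low`, `ci_high`, `p`, `n`.
#' @export
grs_spousal_correlation <- function(instruments, genotypes, pairs,
                                    covariates = NULL,
                                    tiers = c(5e-8, 5e-7, 5e-6, 5e-5)) {
  require_columns(instruments, "pval", "instruments")
  require_columns(pairs, c("index_id", "spouse_id"), "pairs")
  out <- NULL
  for (tier in sort(tiers)) {
    sub <- instruments[instruments$pval < tier, , drop = FALSE]
    if (nrow(sub) == 0L) {
      out <- rbind(out, data.frame(tier = tier, n_snps = 0L, r = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   p = NA_real_, n = 0L))
      next
    }
    grs <- suppressWarnings(build_unweighted_grs(genotypes, sub))
    s <- stats::setNames(grs$score, grs$individual_id)
    res <- adjusted_pearson(unname(s[pairs$index_id]),
                            unname(s[pairs$spouse_id]), covariates,
                            labels = c("grs_index", "grs_spouse"))
    out <- rbind(out, data.frame(tier = tier, n_snps = nrow(sub), r = res$r,
                                 ci_low = res$ci_low, ci_high = res$ci_high,
                                 p = res$p, n = res$n))
  }
  out
}
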