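#' Simulate a biallelic genotype dosage matrix
#'
#' Draws independent variants in Hardy-Weinberg equilibrium: each dosage is
#' the sum of two Bernoulli(MAF) allele draws, so genotype frequencies are
#' \eqn{(1-p)^2, 2p(1-p), p^2} for dosages 0/1/2 of the effect allele.
#' Variants are unlinked (no LD), which is the regime assumed by pre-pruned
#' instrument lists.
#'
#' @param n_individuals number of individuals (rows).
#' @param n_snps number of variants (columns).
#' @param maf minor-allele frequency specification: a scalar in `(0, 0.5]`,
#'   a vector of length `n_snps`, or a length-2 range `c(lo, hi)` from which
#'   per-variant MAFs are drawn uniformly.
#' @param seed integer seed (substreamed internally).
#' @param missing_rate proportion of dosages set missing at random.
#' @param ids optional character vector of individual ids.
#' @return an object of class `genotype_matrix`: a list with `dosage`
#'   (individuals x variants integer matrix, `NA` = missing) and `variants`
#'   (data.frame: `variant_id`, `effect_allele`, `other_allele`, `maf`).
#' @export
#' @examples
#' g <- simulate_genotypes(100, 5, maf = 0.3, seed = 1)
#' table(g$dosage[, 1])
simulate_genotypes <- function(n_individuals, n_snps, maf = c(0.05, 0.5),
                               seed = 1, missing_rate = 0, ids = NULL) {
  if (n_individuals < 1 || n_snps < 1) {
    stop_param("n_individuals and n_snps must be >= 1")
  }
  if (length(maf) == 2L && n_snps != 2L) {
    maf_vec <- with_seed(substream_seed(seed, "maf_draw"),
                         stats::runif(n_snps, maf[1], maf[2]))
  } else if (length(maf) == 1L) {
    maf_vec <- rep(maf, n_snps)
  } else if (length(maf) == n_snps) {
    maf_vec <- maf
  } else {
    stop_param("maf must be a scalar, a length-2 range, or length n_snps")
  }
  if (any(maf_vec <= 0) || any(maf_vec > 0.5)) {
    stop_param("maf must lie in (0, 0.5]")
  }
  n <- as.integer(n_individuals)
  m <- as.integer(n_snps)
  dosage <- with_seed(substream_seed(seed, "simulate_genotypes"), {
    d <- matrix(0L, n, m)
    for (j in seq_len(m)) d[, j] <- stats::rbinom(n, 2L, maf_vec[j])
    if (missing_rate > 0) {
      drop <- stats::runif(n * m) < missing_rate
      d[drop] <- NA_integer_
    }
    d
  })
  ids <- ids %||% sprintf("ind%05d", seq_len(n))
  pairs <- c("A/G", "C/T", "G/A", "T/C", "A/C", "G/T")
  al <- strsplit(pairs[(seq_len(m) - 1L) %% length(pairs) + 1L], "/")
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    effect_allele = vapply(al, `[`, "", 1L),
    other_allele = vapply(al, `[`, "", 2L),
    maf = maf_vec,
    stringsAsFactors = FALSE
  )
  rownames(dosage) <- ids
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " variants\n", sep = "")
  invisible(x)
}

as_dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) return(genotypes$dosage)
  if (is.matrix(genotypes)) return(genotypes)
  stop_schema("expected a genotype_matrix or a dosage matrix")
}

#' Expected variance fraction explained by an unweighted allele score
#'
#' For independent Hardy-Weinberg variants with effect-allele frequencies
#' \eqn{p_j} and a common per-allele effect \eqn{\alpha} on the phenotype,
#' the raw allele count has variance \eqn{\sum_j 2 p_j (1 - p_j)} and the
#' score explains \eqn{\alpha^2 \sum_j 2 p_j (1-p_j) / \sigma^2_{total}} of
#' the phenotype variance.  Used to calibrate simulations to a target
#' instrument strength (realistic scores explain ~0.1-1.4% of trait
#' variance).
#'
#' @param alpha_g per-allele effect on the phenotype (phenotype units per
#'   effect allele).
#' @param maf vector of effect-allele frequencies in `(0, 0.5]`.
#' @param total_variance total phenotype variance (default 1).
#' @return the expected variance fraction.
#' @export
#' @examples
#' expected_grs_variance(0.2, 0.5) # single variant: 0.5 * 0.04
expected_grs_variance <- function(alpha_g, maf, total_variance = 1) {
  if (length(maf) == 0) stop_param("maf vector must be non-empty")
  if (any(maf <= 0) || any(maf > 0.5)) stop_param("maf must lie in (0, 0.5]")
  alpha_g^2 * sum(2 * maf * (1 - maf)) / total_variance
}
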