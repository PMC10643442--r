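#' Simulate a household-descriptor table for a couple cohort
#'
#' Builds the per-individual household record used by spouse-pair
#' reconstruction: true couples share every matching field (years at
#' address, occupants, vehicles, accommodation type and rental status,
#' 1-km home grid coordinates, recruitment centre) and report living with a
#' spouse.  Labelled decoy individuals can be injected to exercise every
#' exclusion rule:
#'
#' * `n_triples` — groups of three individuals with identical descriptors
#'   (the pair cannot be resolved);
#' * `n_same_sex` — same-sex pairs with matching descriptors;
#' * `n_related` — opposite-sex pairs with matching descriptors but high
#'   genetic relatedness (an IBD record with relatedness 0.15 is emitted);
#' * `n_parent_death` — opposite-sex pairs reporting identical paternal and
#'   maternal ages at death (sibling signature).
#'
#' @param cohort a `couple_cohort` from [simulate_couples()].
#' @param decoy_spec list with any of `n_triples`, `n_same_sex`,
#'   `n_related`, `n_parent_death` (defaults 0).
#' @param seed integer seed.
#' @return a list with `households` (one row per individual), `ibd`
#'   (pairwise relatedness records for the decoy related pairs plus true
#'   couples at background relatedness), and `decoys` (id, type).
#' @export
simulate_household_table <- function(cohort, decoy_spec = list(), seed = 1) {
  stopifnot(inherits(cohort, "couple_cohort"), nrow(cohort) > 0)
  spec <- utils::modifyList(list(n_triples = 0, n_same_sex = 0,
                                 n_related = 0, n_parent_death = 0),
                            decoy_spec)
  wide <- couples_wide(cohort, traits = character(0))
  nc <- nrow(wide)
  with_seed(substream_seed(seed, "simulate_household_table"), {
    house <- data.frame(
      couple_id = wide$couple_id,
      years_at_address = sample(1:40, nc, replace = TRUE),
      n_occupants = sample(2:6, nc, replace = TRUE,
                           prob = c(0.45, 0.2, 0.2, 0.1, 0.05)),
      n_vehicles = sample(0:4, nc, replace = TRUE,
                          prob = c(0.1, 0.45, 0.35, 0.07, 0.03)),
      accommodation = sample(c("house", "flat"), nc, TRUE, prob = c(0.8, 0.2)),
      rented = sample(c("owned", "rented"), nc, TRUE, prob = c(0.75, 0.25)),
      coord_north = sample.int(1200, nc, replace = TRUE),
      coord_east = sample.int(700, nc, replace = TRUE),
      stringsAsFactors = FALSE
    )
    centre <- wide$centre %||% sprintf("centre%02d",
                                       sample.int(22, nc, replace = TRUE))
    per_person <- function(ids, sex, h_idx) {
      n <- length(ids)
      data.frame(
        individual_id = ids,
        lives_with = "spouse",
        years_at_address = house$years_at_address[h_idx],
        n_occupants = house$n_occupants[h_idx],
        n_vehicles = house$n_vehicles[h_idx],
        accommodation = house$accommodation[h_idx],
        rented = house$rented[h_idx],
        coord_north = house$coord_north[h_idx],
        coord_east = house$coord_east[h_idx],
        centre = centre[h_idx],
        sex = sex,
        father_death_age = ifelse(stats::runif(n) < 0.5,
                                  sample(55:95, n, replace = TRUE), NA),
        mother_death_age = ifelse(stats::runif(n) < 0.5,
                                  sample(55:95, n, replace = TRUE), NA),
        genotyped = TRUE,
        stringsAsFactors = FALSE
      )
    }
    households <- rbind(per_person(wide$female_id, "female", seq_len(nc)),
                        per_person(wide$male_id, "male", seq_len(nc)))

    ibd <- data.frame(id_a = wide$female_id, id_b = wide$male_id,
                      ibd1 = stats::runif(nc, 0, 0.01),
                      ibd2 = 0,
                      relatedness = stats::runif(nc, 0, 0.01),
                      stringsAsFactors = FALSE)

    decoys <- data.frame(individual_id = character(0), type = character(0),
                         stringsAsFactors = FALSE)
    decoy_counter <- 0L
    new_decoy_house <- function(k, sexes, type) {
      decoy_counter <<- decoy_counter + 1L
      idx <- nrow(house) + 1L
      house[idx, ] <<- list(paste0("decoyhh", decoy_counter),
                            sample(1:40, 1), sample(2:6, 1), sample(0:4, 1),
                            sample(c("house", "flat"), 1),
                            sample(c("owned", "rented"), 1),
                            sample.int(1200, 1), sample.int(700, 1))
      centre <<- c(centre, sprintf("centre%02d", sample.int(22, 1)))
      ids <- sprintf("decoy_%s_%03d_%d", type, decoy_counter, seq_len(k))
      rec <- per_person(ids, sexes, rep(idx, k))
      households <<- rbind(households, rec)
      decoys <<- rbind(decoys, data.frame(individual_id = ids, type = type,
                                          stringsAsFactors = FALSE))
      ids
    }
    for (i in seq_len(spec$n_triples)) {
      new_decoy_house(3L, c("female", "male", "male"), "triple")
    }
    for (i in seq_len(spec$n_same_sex)) {
      new_decoy_house(2L, c("female", "female"), "same_sex")
    }
    for (i in seq_len(spec$n_related)) {
      ids <- new_decoy_house(2L, c("female", "male"), "related")
      ibd <- rbind(ibd, data.frame(id_a = ids[1], id_b = ids[2],
                                   ibd1 = 0.5, ibd2 = 0.02,
                                   relatedness = 0.15,
                                   stringsAsFactors = FALSE))
    }
    for (i in seq_len(spec$n_parent_death)) {
      ids <- new_decoy_house(2L, c("female", "male"), "parent_death")
      rows <- match(ids, households$individual_id)
      households$father_death_age[rows] <- sample(60:90, 1)
      households$mother_death_age[rows] <- sample(60:90, 1)
    }
    list(households = households, ibd = ibd, decoys = decoys)
  })
}

#' Simulate parent-offspring trios with IBD summaries
#'
#' Generates parental genotypes at common variants and child genotypes by
#' Mendelian transmission (one allele drawn from each parent's pair), plus a
#' pairwise IBD table in which true parent-child pairs share ~100% of the
#' genome IBD1 and parents share ~0%.  Decoys exercise the trio filters:
#' sibling pairs posing as candidate parents (mutual IBD1 ~0.5, IBD2 ~0.25)
#' and parent pairs with elevated mutual IBD1.
#'
#' @param n_trios number of true trios.
#' @param decoy_spec list with `n_sib_parents` (trios whose candidate
#'   parents are siblings of each other) and `n_related_parents` (trios
#'   whose parents share IBD1 ~0.3) — defaults 0.
#' @param seed integer seed.
#' @param n_snps variants simulated per genotype (default 120, MAF 0.35-0.5
#'   so at least 100 qualify for concordance checking).
#' @return a list with `ibd` (id_a, id_b, ibd1, ibd2, relatedness),
#'   `genotypes` (a `genotype_matrix` covering children and parents) and
#'   `truth` (child_id, mother_id, father_id, decoy type or `"true"`).
#' @export
simulate_trios <- function(n_trios, decoy_spec = list(), seed = 1,
                           n_snps = 120) {
  if (n_trios < 1) stop_param("n_trios must be >= 1")
  spec <- utils::modifyList(list(n_sib_parents = 0, n_related_parents = 0),
                            decoy_spec)
  total <- n_trios + spec$n_sib_parents + spec$n_related_parents
  with_seed(substream_seed(seed, "simulate_trios"), {
    maf <- stats::runif(n_snps, 0.35, 0.49)
    transmit <- function(d) stats::rbinom(length(d), 1L, d / 2)
    ids <- character(0); dosages <- list()
    ibd <- NULL; truth <- NULL
    jitter <- function(n, lo, hi) stats::runif(n, lo, hi)
    for (i in seq_len(total)) {
      type <- if (i <= n_trios) "true"
              else if (i <= n_trios + spec$n_sib_parents) "sib_parents"
              else "related_parents"
      cid <- sprintf("child%03d", i)
      mid <- sprintf("mother%03d", i)
      fid <- sprintf("father%03d", i)
      gm <- stats::rbinom(n_snps, 2L, maf)
      gf <- stats::rbinom(n_snps, 2L, maf)
      gc <- transmit(gm) + transmit(gf)
      if (type == "sib_parents") {
        # the "parents" are actually siblings of each other and of the
        # index: high mutual IBD1/IBD2, and the index shares enough IBD1
        # with each to pass the per-parent screen
        mutual <- c(ibd1 = 0.5, ibd2 = 0.25)
        child_par <- function() c(ibd1 = jitter(1, 0.44, 0.52), ibd2 = 0.05)
      } else if (type == "related_parents") {
        mutual <- c(ibd1 = jitter(1, 0.25, 0.35), ibd2 = 0.01)
        child_par <- function() c(ibd1 = jitter(1, 0.95, 1) - 0.02,
                                  ibd2 = 0.01)
      } else {
        mutual <- c(ibd1 = jitter(1, 0, 0.02), ibd2 = 0)
        child_par <- function() c(ibd1 = jitter(1, 0.95, 0.985), ibd2 = 0.01)
      }
      cp1 <- child_par(); cp2 <- child_par()
      ibd <- rbind(ibd, data.frame(
        id_a = c(cid, cid, mid),
        id_b = c(mid, fid, fid),
        ibd1 = c(cp1[["ibd1"]], cp2[["ibd1"]], mutual[["ibd1"]]),
        ibd2 = c(cp1[["ibd2"]], cp2[["ibd2"]], mutual[["ibd2"]]),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(child_id = cid, mother_id = mid,
                                       father_id = fid, type = type,
                                       stringsAsFactors = FALSE))
      ids <- c(ids, cid, mid, fid)
      dosages <- c(dosages, list(gc, gm, gf))
    }
    ibd$relatedness <- ibd$ibd1 / 2 + ibd$ibd2
    dosage <- do.call(rbind, dosages)
    rownames(dosage) <- ids
    pairs <- c("A/G", "C/T", "G/A", "T/C")
    al <- strsplit(pairs[(seq_len(n_snps) - 1L) %% 4L + 1L], "/")
    genotypes <- structure(list(
      dosage = dosage,
      variants = data.frame(variant_id = sprintf("rs%06d", seq_len(n_snps)),
                            effect_allele = vapply(al, `[`, "", 1L),
                            other_allele = vapply(al, `[`, "", 2L),
                            maf = maf, stringsAsFactors = FALSE)
    ), class = "genotype_matrix")
    colnames(genotypes$dosage) <- genotypes$variants$variant_id
    list(ibd = ibd, genotypes = genotypes, truth = truth)
  })
}
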