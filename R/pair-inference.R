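#' Reconstruct spouse pairs from household descriptors
#'
#' Emits pairs of individuals who (a) report living with their spouse,
#' (b)-(e) report the same duration at address, number of occupants, number
#' of vehicles, and accommodation type / rental status, (f) have identical
#' 1-km home grid coordinates, (g) are registered at the same recruitment
#' centre, and (h) are genotyped.  Candidate pairs are then excluded when:
#'
#' * more than two individuals share identical information across all
#'   matching fields (`"ambiguous_household"` — the spouses cannot be
#'   resolved; this also covers an individual matching candidates in what
#'   would otherwise be distinct households, since identical fields place
#'   them in the same group);
#' * the two candidates are the same sex (`"same_sex"`);
#' * both candidates report the same paternal *and* the same maternal age
#'   at death, all four values non-missing (`"parental_death_age"` — a
#'   sibling signature);
#' * their pairwise relatedness exceeds `relatedness_max`
#'   (`"relatedness"` — siblings or parent-child rather than spouses).
#'
#' Field matching is exact equality after coordinate quantisation; no
#' tolerance is applied.
#'
#' @param households data.frame with columns `individual_id`, `lives_with`,
#'   `years_at_address`, `n_occupants`, `n_vehicles`, `accommodation`,
#'   `rented`, `coord_north`, `coord_east`, `centre`, `sex`,
#'   `father_death_age`, `mother_death_age`, `genotyped`.
#' @param ibd optional data.frame with `id_a`, `id_b` and a `relatedness`
#'   column (pairs absent from the table are treated as unrelated).
#' @param relatedness_max exclusion threshold for pairwise relatedness
#'   (default 0.1).
#' @return a list with `pairs` (data.frame: `index_id`, `spouse_id`,
#'   `female_id`, `male_id`, `couple_key`) and `exclusions` (data.frame:
#'   `individual_id`, `rule`); every rejected candidate carries at least
#'   one rule tag.
#' @export
derive_spouse_pairs <- function(households, ibd = NULL,
                                relatedness_max = 0.1) {
  match_fields <- c("years_at_address", "n_occupants", "n_vehicles",
                    "accommodation", "rented", "coord_north", "coord_east",
                    "centre")
  require_columns(households,
                  c("individual_id", "lives_with", match_fields, "sex",
                    "father_death_age", "mother_death_age", "genotyped"),
                  "households")
  h <- households[households$lives_with == "spouse" &
                    households$genotyped %in% TRUE, , drop = FALSE]
  key <- do.call(paste, c(h[match_fields], sep = "\r"))
  excl <- list()
  note <- function(ids, rule) {
    excl[[length(excl) + 1L]] <<- data.frame(individual_id = ids, rule = rule,
                                             stringsAsFactors = FALSE)
  }
  rel_lookup <- function(a, b) {
    if (is.null(ibd)) return(0)
    require_columns(ibd, c("id_a", "id_b", "relatedness"), "ibd")
    hit <- (ibd$id_a == a & ibd$id_b == b) | (ibd$id_a == b & ibd$id_b == a)
    if (!any(hit)) 0 else max(ibd$relatedness[hit])
  }
  pairs <- NULL
  for (k in unique(key)) {
    members <- h[key == k, , drop = FALSE]
    if (nrow(members) == 1L) {
      note(members$individual_id, "no_match")
    } else if (nrow(members) > 2L) {
      note(members$individual_id, "ambiguous_household")
    } else {
      a <- members[1, ]; b <- members[2, ]
      rules <- character(0)
      if (a$sex == b$sex) rules <- c(rules, "same_sex")
      same_deaths <- !is.na(a$father_death_age) &&
        !is.na(b$father_death_age) && !is.na(a$mother_death_age) &&
        !is.na(b$mother_death_age) &&
        a$father_death_age == b$father_death_age &&
        a$mother_death_age == b$mother_death_age
      if (same_deaths) rules <- c(rules, "parental_death_age")
      if (rel_lookup(a$individual_id, b$individual_id) > relatedness_max) {
        rules <- c(rules, "relatedness")
      }
      if (length(rules)) {
        for (r in rules) note(c(a$individual_id, b$individual_id), r)
      } else {
        fem <- if (a$sex == "female") a else b
        mal <- if (a$sex == "female") b else a
        pairs <- rbind(pairs, data.frame(
          index_id = fem$individual_id, spouse_id = mal$individual_id,
          female_id = fem$individual_id, male_id = mal$individual_id,
          couple_key = k, stringsAsFactors = FALSE))
      }
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(individual_id = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  list(pairs = pairs %||% data.frame(index_id = character(0),
                                     spouse_id = character(0),
                                     female_id = character(0),
                                     male_id = character(0),
                                     couple_key = character(0),
                                     stringsAsFactors = FALSE),
       exclusions = exclusions)
}

#' Identify parent-offspring trios from IBD sharing
#'
#' Treats every individual as a potential child: candidate parents are
#' those sharing at least `ibd1_min` of the genome IBD1 and at most
#' `ibd2_max` IBD2 with the index individual; a candidate parent pair is
#' retained only when the two parents share at most `parents_ibd1_max` of
#' the genome IBD1 with each other (eliminating, e.g., sibling pairs or a
#' parent paired with the index's own child).
#'
#' @param ibd data.frame with `id_a`, `id_b`, `ibd1`, `ibd2` (symmetric;
#'   pairs absent from the table are treated as sharing nothing).
#' @param sex optional named character vector (or data.frame with
#'   `individual_id`, `sex`) used to label the parents as mother/father.
#' @param ibd1_min minimum child-parent IBD1 (default 0.425).
#' @param ibd2_max maximum child-parent IBD2 (default 0.10).
#' @param parents_ibd1_max maximum mutual parent-parent IBD1 (default 0.20).
#' @return data.frame with `child_id`, `parent1_id`, `parent2_id` (and
#'   `mother_id`/`father_id` when `sex` is given).
#' @export
identify_trios <- function(ibd, sex = NULL, ibd1_min = 0.425,
                           ibd2_max = 0.10, parents_ibd1_max = 0.20) {
  require_columns(ibd, c("id_a", "id_b", "ibd1", "ibd2"), "ibd")
  if (any(ibd$ibd1 + ibd$ibd2 > 1 + 1e-9)) {
    stop_schema("ibd1 + ibd2 must not exceed 1")
  }
  sym <- rbind(ibd[c("id_a", "id_b", "ibd1", "ibd2")],
               stats::setNames(ibd[c("id_b", "id_a", "ibd1", "ibd2")],
                               c("id_a", "id_b", "ibd1", "ibd2")))
  if (is.data.frame(sex)) {
    sex <- stats::setNames(sex$sex, sex$individual_id)
  }
  out <- NULL
  for (child in unique(sym$id_a)) {
    cand <- sym[sym$id_a == child & sym$ibd1 >= ibd1_min &
                  sym$ibd2 <= ibd2_max, , drop = FALSE]
    if (nrow(cand) < 2L) next
    ids <- cand$id_b
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        mut <- sym[sym$id_a == ids[i] & sym$id_b == ids[j], , drop = FALSE]
        mutual_ibd1 <- if (nrow(mut)) max(mut$ibd1) else 0
        if (mutual_ibd1 <= parents_ibd1_max) {
          out <- rbind(out, data.frame(child_id = child,
                                       parent1_id = ids[i],
                                       parent2_id = ids[j],
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  out <- out %||% data.frame(child_id = character(0),
                             parent1_id = character(0),
                             parent2_id = character(0),
                             stringsAsFactors = FALSE)
  if (!is.null(sex) && nrow(out)) {
    s1 <- unname(sex[out$parent1_id]); s2 <- unname(sex[out$parent2_id])
    out$mother_id <- ifelse(s1 == "female", out$parent1_id, out$parent2_id)
    out$father_id <- ifelse(s1 == "female", out$parent2_id, out$parent1_id)
  }
  out
}

# Transmission-possible child dosages for one parental dosage.
transmissible <- function(d) switch(as.character(d), "0" = 0L, "1" = 0:1,
                                    "2" = 1L, stop_param("dosage not in 0:2"))

#' Mendelian concordance of a candidate trio
#'
#' A variant is concordant when the child's dosage can be produced by one
#' transmitted allele from each parent (e.g. child 2 with a dosage-0 parent
#' is impossible).  The check is run on `n_snps` randomly selected variants
#' with per-variant call rate at least `min_call_rate` and MAF above
#' `min_maf`; the trio is accepted when at least `min_concordant` variants
#' are concordant.
#'
#' @param genotypes a `genotype_matrix` (or dosage matrix) containing the
#'   child and both parents; MAF and call rate are computed from the
#'   observed dosages.
#' @param trios data.frame with `child_id`, `mother_id`, `father_id` (or
#'   `parent1_id`/`parent2_id`).
#' @param n_snps number of variants tested (default 100).
#' @param min_maf minimum observed MAF for eligible variants (default 0.3).
#' @param min_call_rate minimum per-variant call rate (default 0.999).
#' @param min_concordant acceptance threshold (default 95).
#' @param seed seed for the variant draw.
#' @param variant_ids optional explicit variant panel (columns of the
#'   dosage matrix); bypasses the eligibility filter and random draw.
#' @return `trios` with added `n_tested`, `n_concordant`, `accepted`.
#' @export
mendelian_concordance_check <- function(genotypes, trios, n_snps = 100,
                                        min_maf = 0.3, min_call_rate = 0.999,
                                        min_concordant = 95, seed = 1,
                                        variant_ids = NULL) {
  dosage <- as_dosage_matrix(genotypes)
  p1 <- trios$mother_id %||% trios$parent1_id
  p2 <- trios$father_id %||% trios$parent2_id
  if (is.null(p1) || is.null(p2)) {
    stop_schema("trios must have mother/father or parent1/parent2 columns")
  }
  if (!is.null(variant_ids)) {
    chosen <- variant_ids
    n_snps <- length(chosen)
  } else {
    call_rate <- colMeans(!is.na(dosage))
    freq <- colMeans(dosage, na.rm = TRUE) / 2
    maf <- pmin(freq, 1 - freq)
    eligible <- which(call_rate >= min_call_rate & maf > min_maf)
    if (length(eligible) < n_snps) {
      stop_param("only ", length(eligible), " variants pass the call-rate ",
                 "and MAF filters; ", n_snps, " required")
    }
    chosen <- with_seed(substream_seed(seed, "mendelian_concordance_check"),
                        sample(eligible, n_snps))
  }
  concordant_variant <- function(gc, gm, gf) {
    if (is.na(gc) || is.na(gm) || is.na(gf)) return(NA)
    gc %in% outer(transmissible(gm), transmissible(gf), `+`)
  }
  res <- trios
  res$n_tested <- n_snps
  res$n_concordant <- vapply(seq_len(nrow(trios)), function(i) {
    gc <- dosage[trios$child_id[i], chosen]
    gm <- dosage[p1[i], chosen]
    gf <- dosage[p2[i], chosen]
    sum(mapply(concordant_variant, gc, gm, gf), na.rm = TRUE)
  }, integer(1))
  res$accepted <- res$n_concordant >= min_concordant
  res
}
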