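# Spouse-pair reconstruction, trio identification and Mendelian
# concordance.

make_household_row <- function(id, sex, key = 1, father = NA, mother = NA,
                               lives_with = "spouse", genotyped = TRUE) {
  data.frame(individual_id = id, lives_with = lives_with,
             years_at_address = 10 + key, n_occupants = 2, n_vehicles = 1,
             accommodation = "house", rented = "owned",
             coord_north = 100 + key, coord_east = 200, centre = "centre01",
             sex = sex, father_death_age = father, mother_death_age = mother,
             genotyped = genotyped, stringsAsFactors = FALSE)
}

test_that("matching opposite-sex unrelated candidates form one pair", {
  hh <- rbind(make_household_row("f1", "female"),
              make_household_row("m1", "male"))
  res <- derive_spouse_pairs(hh)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$female_id, "f1")
  expect_equal(res$pairs$male_id, "m1")
})

test_that("exclusion rules fire and are logged", {
  hh <- rbind(
    make_household_row("f1", "female", key = 1),
    make_household_row("m1", "male", key = 1),   # related pair
    make_household_row("f2", "female", key = 2),
    make_household_row("f3", "female", key = 2), # same sex
    make_household_row("a", "female", key = 3),
    make_household_row("b", "male", key = 3),
    make_household_row("c", "male", key = 3),    # triple
    make_household_row("f4", "female", key = 4, father = 80, mother = 75),
    make_household_row("m4", "male", key = 4, father = 80, mother = 75)
  )
  ibd <- data.frame(id_a = "f1", id_b = "m1", relatedness = 0.15)
  res <- derive_spouse_pairs(hh, ibd)
  expect_equal(nrow(res$pairs), 0)
  rules <- split(res$exclusions$individual_id, res$exclusions$rule)
  expect_setequal(rules$relatedness, c("f1", "m1"))
  expect_setequal(rules$same_sex, c("f2", "f3"))
  expect_setequal(rules$ambiguous_household, c("a", "b", "c"))
  expect_setequal(rules$parental_death_age, c("f4", "m4"))
  # every rejected candidate carries at least one rule tag
  expect_setequal(unique(res$exclusions$individual_id), hh$individual_id)
})

test_that("parental-death exclusion needs all four ages non-missing", {
  hh <- rbind(make_household_row("f1", "female", father = 80, mother = NA),
              make_household_row("m1", "male", father = 80, mother = NA))
  res <- derive_spouse_pairs(hh)
  expect_equal(nrow(res$pairs), 1)
})

test_that("relatedness at the threshold is kept, above is excluded", {
  hh <- rbind(make_household_row("f1", "female"),
              make_household_row("m1", "male"))
  at <- derive_spouse_pairs(hh, data.frame(id_a = "f1", id_b = "m1",
                                           relatedness = 0.1))
  expect_equal(nrow(at$pairs), 1)
  above <- derive_spouse_pairs(hh, data.frame(id_a = "f1", id_b = "m1",
                                              relatedness = 0.100001))
  expect_equal(nrow(above$pairs), 0)
})

test_that("planted couples are fully recovered and no decoy is accepted", {
  co <- quick_cohort("null", n_couples = 100, n_snps = 5, seed = 21)
  hh <- simulate_household_table(co,
                                 decoy_spec = list(n_triples = 3,
                                                   n_same_sex = 3,
                                                   n_related = 3,
                                                   n_parent_death = 3),
                                 seed = 22)
  res <- derive_spouse_pairs(hh$households, hh$ibd)
  truth <- couples_wide(co)
  expect_equal(nrow(res$pairs), 100)               # sensitivity 1.0
  expect_setequal(paste(res$pairs$female_id, res$pairs$male_id),
                  paste(truth$female_id, truth$male_id))
  accepted_ids <- c(res$pairs$female_id, res$pairs$male_id)
  expect_length(intersect(accepted_ids, hh$decoys$individual_id), 0)
  # each decoy type appears in the exclusion log
  logged <- res$exclusions$individual_id
  expect_true(all(hh$decoys$individual_id %in% logged))
})

test_that("trio identification applies the three IBD thresholds", {
  ibd <- data.frame(
    id_a = c("child", "child", "mother"),
    id_b = c("mother", "father", "father"),
    ibd1 = c(0.50, 0.48, 0.05),
    ibd2 = c(0.05, 0.02, 0.00))
  hit <- identify_trios(ibd)
  expect_equal(nrow(hit), 1)
  expect_setequal(c(hit$parent1_id, hit$parent2_id), c("mother", "father"))

  # candidate parent below the 42.5% IBD1 bound is rejected
  ibd$ibd1[1] <- 0.40
  expect_equal(nrow(identify_trios(ibd)), 0)
  ibd$ibd1[1] <- 0.50

  # parents sharing 30% IBD1 with each other are rejected
  ibd$ibd1[3] <- 0.30
  expect_equal(nrow(identify_trios(ibd)), 0)

  # excess IBD2 with the index is rejected
  ibd$ibd1[3] <- 0.05
  ibd$ibd2[1] <- 0.15
  expect_equal(nrow(identify_trios(ibd)), 0)
})

test_that("simulated trios are recovered and sib decoys rejected", {
  tr <- simulate_trios(8, decoy_spec = list(n_sib_parents = 3,
                                            n_related_parents = 3),
                       seed = 23)
  found <- identify_trios(tr$ibd)
  truth <- tr$truth[tr$truth$type == "true", ]
  expect_setequal(found$child_id, truth$child_id)
  # Mendelian transmission: child never carries an allele no parent holds
  d <- tr$genotypes$dosage
  for (i in seq_len(nrow(tr$truth))) {
    gc <- d[tr$truth$child_id[i], ]
    gm <- d[tr$truth$mother_id[i], ]
    gf <- d[tr$truth$father_id[i], ]
    expect_false(any(gc == 2 & (gm == 0 | gf == 0)))
    expect_false(any(gc == 0 & (gm == 2 | gf == 2)))
  }
})

test_that("Mendelian concordance matches exhaustive transmission oracle", {
  combos <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  # brute-force oracle over explicit parental allele pairs
  alleles <- list(`0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L))
  oracle <- mapply(function(gc, gm, gf) {
    possible <- outer(alleles[[as.character(gm)]],
                      alleles[[as.character(gf)]], `+`)
    gc %in% possible
  }, combos$child, combos$mother, combos$father)

  dosage <- rbind(child = combos$child, mother = combos$mother,
                  father = combos$father)
  colnames(dosage) <- paste0("v", seq_len(ncol(dosage)))
  per_variant <- vapply(seq_len(ncol(dosage)), function(j) {
    res <- mendelian_concordance_check(
      dosage, data.frame(child_id = "child", mother_id = "mother",
                         father_id = "father"),
      variant_ids = colnames(dosage)[j], min_concordant = 1)
    res$n_concordant == 1
  }, TRUE)
  expect_equal(per_variant, unname(oracle))
  # spot examples: forced transmission vs impossible transmission
  expect_true(oracle[combos$child == 1 & combos$mother == 0 &
                       combos$father == 2])
  expect_false(oracle[combos$child == 2 & combos$mother == 0 &
                        combos$father == 2])
})

test_that("concordance checker enforces the marker eligibility filter", {
  g <- simulate_genotypes(30, 50, maf = 0.4, seed = 24)
  expect_error(
    mendelian_concordance_check(g, data.frame(child_id = "ind00001",
                                              mother_id = "ind00002",
                                              father_id = "ind00003"),
                                n_snps = 100),
    class = "dyadmr_parameter_error")
})
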