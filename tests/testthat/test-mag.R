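test_that("quality tiers follow the completeness/redundancy thresholds", {
  expect_equal(quality_tier(95, 5), "high")
  # the boundaries are strict for high quality
  expect_equal(quality_tier(90, 5), "medium")
  expect_equal(quality_tier(95, 10), "below_medium")
  expect_equal(quality_tier(45, 8, medium_floor = 42), "medium")
  expect_equal(quality_tier(45, 8, medium_floor = 50), "below_medium")
  expect_equal(quality_tier(85, 12), "below_medium")
  # vectorised, one tier per MAG
  tiers <- quality_tier(c(95, 90, 45, 20), c(5, 5, 8, 1))
  expect_equal(tiers, c("high", "medium", "below_medium", "below_medium"))
  expect_error(quality_tier(101, 5), "100")
})

test_that("EC wildcard matching is field-wise, not a string prefix", {
  expect_true(ec_matches("1.4.1.2", "1.4.*"))
  expect_false(ec_matches("1.14.13.1", "1.4.*"))
  expect_true(ec_matches("4.3.1.19", "4.3.1*"))
  expect_false(ec_matches("4.3.2.1", "4.3.1*"))
  expect_true(ec_matches("3.5.1.5", "3.5.*"))
  # partial annotations match on their known fields
  expect_true(ec_matches("1.4.-.-", "1.4.*"))
  expect_true(ec_matches("4.3.-.-", "4.3.1*"))
  # full-EC patterns compare all four fields
  expect_true(ec_matches("1.4.1.2", "1.4.1.2"))
  expect_false(ec_matches("1.4.1.3", "1.4.1.2"))
  expect_error(ec_matches("foo.4.1.2", "1.4.*"), "malformed")
  expect_error(ec_matches("1.4.1.2", "1.4"), "\\*")
})

test_that("ec_matches agrees with a brute-force oracle on random pairs", {
  set.seed(17)
  n <- 1e4
  ecs <- random_ec(n)
  pats <- random_ec_pattern(n)
  got <- vapply(seq_len(n), function(i) ec_matches(ecs[i], pats[i]),
                logical(1))
  want <- vapply(seq_len(n), function(i) brute_force_ec_match(ecs[i], pats[i]),
                 logical(1))
  expect_identical(got, want)
})

test_that("the ammonification screen flags the three enzyme classes", {
  ann <- tibble::tibble(
    mag_id = c("m1", "m2", "m2", "m3"),
    gene_id = paste0("g", 1:4),
    ec_numbers = c("1.4.1.2", "3.5.1.5", "4.3.1.19", "2.7.1.1"))
  flags <- ammonification_screen(ann)
  expect_equal(flags$has_ec_1_4, c(TRUE, FALSE, FALSE))
  expect_equal(flags$has_ec_3_5, c(FALSE, TRUE, FALSE))
  expect_equal(flags$has_ec_4_3_1, c(FALSE, TRUE, FALSE))
  counts <- screen_counts(flags)
  expect_equal(counts$n_mags, c(1L, 1L, 1L))
  expect_error(ammonification_screen(ann[0, ]), "empty")
})

test_that("screen counts equal brute-force enumeration and ignore row order", {
  set.seed(23)
  synth <- synth_annotations(30, class_prevalences = c(
    has_ec_1_4 = 0.8, has_ec_3_5 = 0.5, has_ec_4_3_1 = 0.3), seed = 4)
  ann <- synth$annotations
  flags <- ammonification_screen(ann)
  # brute force: loop over every gene x pattern pair
  pats <- c(has_ec_1_4 = "1.4.*", has_ec_3_5 = "3.5.*",
            has_ec_4_3_1 = "4.3.1*")
  for (cls in names(pats)) {
    hit <- rep(FALSE, nrow(flags))
    names(hit) <- flags$mag_id
    for (i in seq_len(nrow(ann))) {
      ecs <- strsplit(ann$ec_numbers[i], ";")[[1]]
      ecs <- ecs[nzchar(ecs)]
      for (e in ecs) {
        if (brute_force_ec_match(e, pats[[cls]])) hit[[ann$mag_id[i]]] <- TRUE
      }
    }
    expect_equal(flags[[cls]], unname(hit[flags$mag_id]), label = cls)
  }
  # invariance under shuffling and duplication of annotation rows
  shuffled <- ann[sample(nrow(ann)), ]
  dup <- dplyr::bind_rows(ann, ann[sample(nrow(ann), 10), ])
  expect_equal(ammonification_screen(shuffled), flags,
               ignore_attr = TRUE)
  expect_equal(ammonification_screen(dup), flags, ignore_attr = TRUE)
})

test_that("module completion applies the 75% rule inclusively", {
  m8 <- module_definition("M8", paste0("K", 1:8))
  expect_equal(module_completion(paste0("K", 1:6), m8),
               list(fraction = 0.75, complete = TRUE))
  expect_equal(module_completion(paste0("K", 1:5), m8),
               list(fraction = 0.625, complete = FALSE))
  expect_equal(module_completion(paste0("K", 1:8), m8),
               list(fraction = 1, complete = TRUE))
  expect_equal(module_completion(character(0), m8)$fraction, 0)
  # duplicates and foreign orthologs do not inflate the fraction
  expect_equal(module_completion(c("K1", "K1", "K99"), m8)$fraction, 1 / 8)
  expect_error(module_definition("M0", character(0)), "ortholog")
})

test_that("module completion is monotone in the annotated set", {
  m <- module_definition("M", paste0("K", 1:6))
  set.seed(9)
  pool <- c(paste0("K", 1:6), paste0("X", 1:6))
  fr_prev <- 0
  present <- character(0)
  for (i in seq_along(pool)) {
    present <- c(present, sample(pool, 1))
    fr <- module_completion(present, m)$fraction
    expect_gte(fr, fr_prev)
    expect_gte(fr, 0)
    expect_lte(fr, 1)
    fr_prev <- fr
  }
})

test_that("the function matrix matches hand-computed fractions", {
  mags <- tibble::tibble(
    mag_id = c("mB", "mA", "mC", "mD"),
    completeness = c(95, 80, 60, 30),
    redundancy = c(2, 5, 3, 1),
    taxonomy = c("Bacteria;P1", "Bacteria;P2", "", "Bacteria;P3"))
  mods <- list(module_definition("M2", c("K1", "K2")),
               module_definition("M1", c("K1", "K3", "K4", "K5")))
  ann <- tibble::tibble(
    mag_id = c("mA", "mA", "mB", "ghost"),
    gene_id = paste0("g", 1:4),
    ortholog_ids = c("K1;K2", "K3", "K1", "K9"))
  expect_warning(fm <- function_matrix(mags, ann, mods), "unknown MAGs")
  # below-medium mD is excluded; rows and columns are lexicographic
  expect_equal(fm$mag_id, c("mA", "mB", "mC"))
  expect_equal(names(fm), c("mag_id", "tier", "taxonomy", "M1", "M2"))
  expect_equal(fm$M2, c(1, 0.5, 0))     # mA has K1,K2; mB has K1; mC none
  expect_equal(fm$M1, c(0.5, 0.25, 0))  # mA has K1,K3 of 4; mB K1 of 4
  expect_equal(fm$tier, c("medium", "high", "medium"))
  expect_equal(attr(fm, "n_skipped"), 1L)
})

test_that("the synthetic cohort plants exact screen outcomes", {
  synth <- synth_annotations(
    67,
    class_prevalences = c(has_ec_1_4 = 1, has_ec_3_5 = 1,
                          has_ec_4_3_1 = 61 / 67),
    seed = 12)
  flags <- ammonification_screen(synth$annotations)
  expect_equal(nrow(flags), 67)
  expect_true(all(flags$has_ec_1_4 | flags$has_ec_3_5))
  expect_equal(sum(flags$has_ec_4_3_1), 61)
  # zero prevalence -> all flags false
  none <- synth_annotations(10, class_prevalences = c(
    has_ec_1_4 = 0, has_ec_3_5 = 0, has_ec_4_3_1 = 0), seed = 2)
  f0 <- ammonification_screen(none$annotations)
  expect_false(any(f0$has_ec_1_4 | f0$has_ec_3_5 | f0$has_ec_4_3_1))
  # reproducible for a fixed seed
  a <- synth_annotations(20, seed = 5)
  b <- synth_annotations(20, seed = 5)
  expect_identical(a, b)
  # infeasible targets warn and use the nearest achievable count
  expect_warning(synth_annotations(10, class_prevalences = c(
    has_ec_1_4 = 0.55, has_ec_3_5 = 1, has_ec_4_3_1 = 1), seed = 2),
    "not achievable")
})

test_that("planted tiers and module fractions survive the full screen", {
  synth <- synth_annotations(
    24, tier_counts = c(high = 8, medium = 12, below_medium = 4),
    class_prevalences = c(has_ec_1_4 = 1, has_ec_3_5 = 1,
                          has_ec_4_3_1 = 0.75),
    module_completion_targets = c(M_nif = 0.75, M_urease = 1,
                                  M_denit = 0.5),
    seed = 33)
  tiers <- quality_tier(synth$mags$completeness, synth$mags$redundancy)
  expect_equal(sum(tiers == "high"), 8)
  expect_equal(sum(tiers == "medium"), 12)
  expect_equal(sum(tiers == "below_medium"), 4)
  fm <- function_matrix(synth$mags, synth$annotations, toy_modules())
  expect_equal(nrow(fm), 20)  # high + medium only
  expect_true(all(fm$M_nif == 0.75))
  expect_true(all(fm$M_urease == 1))
  expect_true(all(fm$M_denit == 0.5))
})
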