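test_that("an exact-genotype donor is found and only that donor", {
  reg <- toy_registry()
  pat <- toy_patient()
  res <- find_matches(pat, reg, search_spec("6/6", "medium", 0))
  # donors 1 and 5 share the patient's exact A/B/DRB1 genotype
  expect_equal(res$donor_ids[[1]], c("D000001", "D000005"))
  expect_equal(res$n_matches, 2)
})

test_that("NMDP codes match when the patient allele is in the expansion", {
  reg <- toy_registry()
  pat <- toy_patient()
  pat$A_2 <- "A*02:05"    # member of A*02:AB, donor 2 has A*03:02 second
  pat$A_1 <- "A*03:02"
  res <- find_matches(pat, reg, search_spec("6/6", "medium", 0))
  expect_equal(res$donor_ids[[1]], "D000002")
  # a patient allele outside the expansion does not match
  pat$A_2 <- "A*02:07"
  res2 <- find_matches(pat, reg, search_spec("6/6", "medium", 0))
  expect_equal(res2$n_matches, 0)
})

test_that("low-resolution donors match at low but never at medium
          resolution", {
  reg <- toy_registry()
  pat <- toy_patient()
  low <- find_matches(pat, reg, search_spec("6/6", "low", 0))
  expect_true("D000003" %in% low$donor_ids[[1]])
  med <- find_matches(pat, reg, search_spec("6/6", "medium", 0))
  expect_false("D000003" %in% med$donor_ids[[1]])
  # the low-resolution donor is typed, so it is not in excluded_untyped
  expect_equal(med$excluded_untyped, 0)
})

test_that("donors untyped at a required locus are excluded and counted", {
  reg <- toy_registry()
  pat <- toy_patient()
  res <- find_matches(pat, reg, search_spec("8/8", "medium", 0))
  expect_false("D000003" %in% res$donor_ids[[1]])   # untyped at C
  expect_equal(res$excluded_untyped, 1)
  res10 <- find_matches(pat, reg, search_spec("10/10", "medium", 0))
  expect_equal(res10$excluded_untyped, 2)           # donor 3 and donor 5
})

test_that("an untyped patient locus is an error", {
  reg <- toy_registry()
  pat <- toy_patient()
  pat$C_1 <- NA_character_
  expect_error(find_matches(pat, reg, search_spec("8/8", "low", 0)),
               "untyped at required locus C")
  expect_no_error(find_matches(pat, reg, search_spec("6/6", "low", 0)))
})

test_that("empty and homozygous registries canonicalise correctly", {
  reg <- toy_registry()[0, ]
  pat <- toy_patient()
  res <- find_matches(pat, reg, search_spec("6/6", "low", 0))
  expect_equal(res$n_matches, 0)
  # homozygous patient matches homozygous donor under either ordering
  reg2 <- toy_registry()
  pat2 <- toy_patient()
  pat2$A_1 <- pat2$A_2 <- "A*09:01"
  reg2$A_1[4] <- reg2$A_2[4] <- "A*09:01"
  reg2$B_1[4] <- "B*05:01"; reg2$B_2[4] <- "B*06:02"
  reg2$DRB1_1[4] <- "DRB1*07:01"; reg2$DRB1_2[4] <- "DRB1*08:01"
  res2 <- find_matches(pat2, reg2, search_spec("6/6", "medium", 0))
  expect_equal(res2$donor_ids[[1]], "D000004")
})

test_that("indexed search equals the naive scan across random fixtures", {
  reg <- random_registry(300, seed = 21)
  cohort <- random_cohort(30, seed = 22)
  index <- build_match_index(reg)
  for (spec in all_search_specs()) {
    for (i in seq_len(nrow(cohort))) {
      fast <- find_matches(cohort[i, ], reg, spec, index)
      slow <- find_matches_naive(cohort[i, ], reg, spec)
      expect_identical(fast$donor_ids[[1]], slow$donor_ids[[1]],
                       info = paste(spec$loci_set, spec$resolution,
                                    spec$max_mismatch, i))
      expect_identical(fast$excluded_untyped, slow$excluded_untyped)
    }
  }
})

test_that("indexed search equals the naive scan on a heterogeneous
          generated registry", {
  cfg <- small_config(registry = list(n = 250L))
  reg <- generate_registry(cfg)
  cohort <- generate_cohort(cfg)[1:12, ]
  index <- build_match_index(reg)
  for (spec in all_search_specs()) {
    for (i in seq_len(nrow(cohort))) {
      fast <- find_matches(cohort[i, ], reg, spec, index)
      slow <- find_matches_naive(cohort[i, ], reg, spec)
      expect_identical(fast$donor_ids[[1]], slow$donor_ids[[1]],
                       info = paste(spec$loci_set, spec$resolution,
                                    spec$max_mismatch, i))
    }
  }
})

test_that("match sets are monotone in resolution, loci set and
          allowance", {
  # fully typed, all-medium registry so loci-set nesting applies
  reg <- random_registry(400, seed = 31)
  cohort <- random_cohort(25, seed = 32)
  index <- build_match_index(reg)
  get <- function(i, ls, res, mm) {
    find_matches(cohort[i, ], reg, search_spec(ls, res, mm),
                 index)$donor_ids[[1]]
  }
  for (i in seq_len(nrow(cohort))) {
    for (ls in c("6/6", "8/8", "10/10")) {
      for (res in c("low", "medium")) {
        expect_true(all(get(i, ls, res, 0) %in% get(i, ls, res, 1)))
      }
      expect_true(all(get(i, ls, "medium", 0) %in% get(i, ls, "low", 0)))
      expect_true(all(get(i, ls, "medium", 1) %in% get(i, ls, "low", 1)))
    }
    for (res in c("low", "medium")) {
      expect_true(all(get(i, "10/10", res, 0) %in% get(i, "8/8", res, 0)))
      expect_true(all(get(i, "8/8", res, 0) %in% get(i, "6/6", res, 0)))
    }
  }
})

test_that("patients matched against themselves always find a donor", {
  cohort <- random_cohort(40, seed = 41)
  reg <- cohort
  names(reg)[1] <- "donor_id"
  reg$self_id <- "White"
  reg$typing_resolution <- "medium"
  attr(reg, "codes") <- hla_code_table(list())
  mt <- batch_match(cohort, reg)
  s <- summarize_matches(mt)
  expect_true(all(s$pct_at_least_one == 100))
})

test_that("disjoint allele alphabets yield no matches anywhere", {
  cohort <- random_cohort(10, seed = 51, groups = 3)
  reg <- random_registry(50, seed = 52, groups = 3)
  for (cl in paste0(rep(hla_loci, each = 2), "_", 1:2)) {
    reg[[cl]] <- sub("\\*0", "*2", reg[[cl]])  # shift into foreign groups
  }
  mt <- batch_match(cohort, reg)
  expect_true(all(mt$n_matches == 0))
})

test_that("batch summaries compute medians over matched patients only", {
  mt <- tibble::tibble(
    patient_id = sprintf("P%d", 1:4),
    loci_set = "6/6", resolution = "low", max_mismatch = 0L,
    n_matches = c(0L, 2L, 10L, 0L), excluded_untyped = 0L
  )
  s <- summarize_matches(mt)
  expect_equal(s$pct_at_least_one, 50)
  expect_equal(s$median_matches, 6)
  expect_equal(s$max_matches, 10)
})

test_that("index construction is idempotent", {
  reg <- toy_registry()
  i1 <- build_match_index(reg)
  i2 <- build_match_index(reg)
  pat <- toy_patient()
  for (spec in all_search_specs()) {
    expect_identical(find_matches(pat, reg, spec, i1),
                     find_matches(pat, reg, spec, i2))
  }
})
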