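test_that("grouped match rates are per-group proportions", {
  mt <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    loci_set = "6/6", resolution = "low", max_mismatch = 0L,
    n_matches = c(rep(1L, 10), rep(0L, 10)),
    excluded_untyped = 0L
  )
  asn <- tibble::tibble(id = sprintf("P%02d", 1:20),
                        grp = rep(c("a", "b"), each = 10))
  gr <- grouped_match_rates(mt, asn, "grp")
  expect_equal(gr$rate, c(1, 0))
  expect_equal(sum(gr$n), 20)

  asn$grp <- rep(c("a", "b"), 10)
  gr2 <- grouped_match_rates(mt, asn, "grp")
  expect_equal(gr2$rate, c(0.5, 0.5))

  mt2 <- mt
  mt2$n_matches <- c(rep(1L, 9), rep(0L, 11))
  asn$grp <- c(rep("a", 10), rep("b", 10))
  expect_equal(grouped_match_rates(mt2, asn, "grp")$rate[1], 0.9)
  asn$grp[1] <- NA
  expect_error(grouped_match_rates(mt2, asn, "grp"), "assignment")
})

test_that("odds ratios match the 2x2 closed form and the logistic fit", {
  mk <- function(a, b, c, d) {
    outcome <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
    group <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d))
    list(outcome = outcome, group = group)
  }
  x <- mk(10, 10, 10, 10)
  expect_equal(odds_ratio(x$outcome, x$group)$or, 1)
  x <- mk(20, 10, 10, 20)
  or <- odds_ratio(x$outcome, x$group)
  expect_equal(or$or, 4)
  expect_equal(or$logistic_or, 4, tolerance = 1e-6)

  # closed form and IRLS agree across random tables
  tabs <- withr::with_seed(77, {
    matrix(sample(3:40, 4 * 25, replace = TRUE), ncol = 4)
  })
  for (i in seq_len(nrow(tabs))) {
    x <- mk(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    or <- odds_ratio(x$outcome, x$group)
    expect_equal(or$or, or$logistic_or, tolerance = 1e-6)
    # swapping exposure inverts the odds ratio
    swapped <- odds_ratio(x$outcome, !x$group)
    expect_equal(swapped$or, 1 / or$or, tolerance = 1e-12)
  }
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  outcome <- rep(c(TRUE, FALSE, TRUE), c(10, 10, 5))
  group <- rep(c(TRUE, TRUE, FALSE), c(10, 10, 5))
  or <- odds_ratio(outcome, group)
  expect_true(or$corrected)
  expect_true(is.finite(or$or) && or$or > 0)
  expect_true(is.na(or$logistic_or))
  expect_error(odds_ratio(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "both outcome levels")
})

test_that("percent decrease reproduces printed-rate arithmetic", {
  expect_equal(percent_decrease(91.1, 82.9)$percent, 9)
  expect_equal(percent_decrease(16.9, 7.3)$percent, 57)
  expect_equal(percent_decrease(92.1, 81.7)$percent, 11)
  expect_equal(percent_decrease(93.0, 76.5)$percent, 18)
  expect_equal(percent_decrease(0.5, 0.5)$percent, 0)
  expect_error(percent_decrease(0, 0.5), "positive")
})

test_that("matched-size subsampling converges to the plain estimate when
          rates are size-independent", {
  ref <- withr::with_seed(88, runif(400) < 0.6)
  cmp <- withr::with_seed(89, runif(100) < 0.3)
  plain <- percent_decrease(mean(ref), mean(cmp))$raw
  matched <- percent_decrease(ref, cmp, matched_sizes = TRUE, reps = 1000,
                              seed = 90)$raw
  expect_equal(matched, plain, tolerance = 0.03)
  # single-subsample mode is available for sensitivity checks
  one <- percent_decrease(ref, cmp, matched_sizes = TRUE, reps = 1,
                          seed = 91)
  expect_true(is.finite(one$raw))
})

test_that("donor composition averages individual frequency vectors,
          not pooled donors", {
  reg <- tibble::tibble(
    donor_id = sprintf("D%06d", 1:6),
    self_id = c("Black", "Black", "White", "White", "White", "White")
  )
  mt <- tibble::tibble(
    patient_id = c("P1", "P2"),
    loci_set = "6/6", resolution = "low", max_mismatch = 0L,
    n_matches = c(1L, 2L),
    donor_ids = list("D000001", c("D000003", "D000004"))
  )
  asn <- tibble::tibble(id = c("P1", "P2"), grp = c("g", "g"))
  comp <- donor_composition(mt, reg, asn, "grp")
  # patient1 is 100% Black donors, patient2 100% White: average 50/50,
  # not the pooled 1/3 vs 2/3
  expect_equal(comp$share[comp$donor_self_id == "Black"], 0.5)
  expect_equal(comp$share[comp$donor_self_id == "White"], 0.5)

  mt2 <- mt
  mt2$donor_ids <- list(c("D000001", "D000001", "D000003", "D000004"), "D000005")
  mt2$n_matches <- c(4L, 1L)
  comp2 <- donor_composition(mt2, reg, asn, "grp")
  sums <- tapply(comp2$share, comp2$group, sum)
  expect_equal(as.vector(sums), 1, tolerance = 1e-12)
})

test_that("donor composition shares always sum to one per group", {
  reg <- random_registry(40, seed = 61)
  mt <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    loci_set = "6/6", resolution = "low", max_mismatch = 0L,
    n_matches = withr::with_seed(62, sample(0:5, 10, replace = TRUE)),
    donor_ids = NA
  )
  mt$donor_ids <- withr::with_seed(63, lapply(mt$n_matches, function(k) {
    sample(reg$donor_id, k)
  }))
  asn <- tibble::tibble(id = mt$patient_id,
                        grp = rep(c("x", "y"), 5))
  comp <- donor_composition(mt, reg, asn, "grp")
  sums <- tapply(comp$share, comp$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the donor-count rank test behaves at its extremes", {
  same <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- donor_count_test(same, same)
  expect_gt(res$p_value, 0.9)
  a <- 21:40; b <- 1:20
  res2 <- donor_count_test(a, b)
  expect_lt(res2$p_value, 0.001)
  # U statistics from the two directions partition n_a * n_b
  u1 <- donor_count_test(a, b)$u
  u2 <- donor_count_test(b, a)$u
  expect_equal(u1 + u2, length(a) * length(b))
  counts <- withr::with_seed(64, list(a = sample(1:30, 25, TRUE),
                                      b = sample(1:30, 18, TRUE)))
  expect_equal(donor_count_test(counts$a, counts$b)$u +
                 donor_count_test(counts$b, counts$a)$u, 25 * 18)
})

test_that("the two-proportion z test is antisymmetric and zero under
          equality", {
  expect_equal(two_prop_ztest(0.3, 100, 0.3, 200)$z, 0)
  z1 <- two_prop_ztest(0.2, 150, 0.35, 90)$z
  z2 <- two_prop_ztest(0.35, 90, 0.2, 150)$z
  expect_equal(z1, -z2)
  expect_lt(z1, 0)
})

test_that("sibling match probability follows 1 - (3/4)^k", {
  expect_equal(sibling_match_prob(0), 0)
  expect_equal(sibling_match_prob(1), 0.25)
  expect_equal(sibling_match_prob(3), 0.578125)
  expect_equal(sibling_match_prob(1:4),
               1 - (3 / 4)^(1:4))
  expect_error(sibling_match_prob(-1), "non-negative")
  expect_error(sibling_match_prob(1.5), "non-negative")
})
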