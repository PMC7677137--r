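test_that("pool generation is a deterministic function of config and seed", {
  cfg <- small_config()
  p1 <- generate_pools(cfg, seed = 11)
  p2 <- generate_pools(cfg, seed = 11)
  p3 <- generate_pools(cfg, seed = 12)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  expect_false(identical(tibble::as_tibble(p1), tibble::as_tibble(p3)))
})

test_that("the African pool is larger and more heterozygous than the
          European pool", {
  pools <- generate_pools(small_config())
  n_afr <- sum(pools$ancestry == "AFR")
  n_eur <- sum(pools$ancestry == "EUR")
  expect_gt(n_afr, n_eur)
  het <- pool_heterozygosity(pools)
  wide <- tidyr::pivot_wider(het, names_from = "ancestry",
                             values_from = "heterozygosity")
  expect_true(all(wide$AFR > wide$EUR))
  # frequencies are a proper distribution within each pool
  sums <- tapply(pools$freq, pools$ancestry, sum)
  expect_equal(as.vector(sums), c(1, 1), tolerance = 1e-9)
})

test_that("allele sharing 0 gives disjoint allele-group universes", {
  cfg <- small_config(pools = list(allele_sharing = 0))
  pools <- generate_pools(cfg)
  for (locus in hla_loci) {
    afr <- unique(hla_truncate(pools[[locus]][pools$ancestry == "AFR"], "low"))
    eur <- unique(hla_truncate(pools[[locus]][pools$ancestry == "EUR"], "low"))
    expect_length(intersect(afr, eur), 0)
  }
})

test_that("degenerate pool configurations are rejected", {
  expect_error(sim_config(pools = list(n_hap_afr = 0L)), "at least 2")
  expect_error(sim_config(registry = list(composition = c(White = 0.5))),
               "sum to 1")
  expect_error(sim_config(registry = list(typed_c = 1.5)), "\\[0, 1\\]")
})

test_that("cohort ancestry vectors lie on the simplex and typing is
          complete", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  expect_equal(coh$q_afr + coh$q_eur + coh$q_nat, rep(1, nrow(coh)),
               tolerance = 1e-9)
  expect_true(all(coh$q_afr >= 0 & coh$q_afr <= 1))
  for (cl in paste0(rep(hla_loci, each = 2), "_", 1:2)) {
    expect_false(anyNA(coh[[cl]]))
  }
  # block inheritance: without recombination each MHC haplotype has a
  # single ancestry
  expect_true(all(coh$mhc_afr_1 %in% c(0, 1)))
  expect_true(all(coh$mhc_afr_2 %in% c(0, 1)))
})

test_that("cohort generation is reproducible and seeds are independent
          per stage", {
  cfg <- small_config()
  pools <- generate_pools(cfg)
  sid <- calibrate_self_id(cfg)
  c1 <- generate_cohort(cfg, pools, sid)
  c2 <- generate_cohort(cfg, pools, sid)
  expect_identical(c1, c2)
})

test_that("an all-African admixture distribution yields African MHC
          haplotypes", {
  cfg <- small_config(admixture = list(cohorts = list(
    general = list(n = 60L, afr_mean = 0.9999, afr_conc = 1e5, scd = FALSE),
    scd = NULL)))
  coh <- generate_cohort(cfg, selfid = calibrate_self_id(small_config()))
  expect_gt(mean(c(coh$mhc_afr_1, coh$mhc_afr_2)), 0.98)
})

test_that("with recombination on, MHC haplotypes can carry mixed
          ancestry fractions", {
  cfg <- small_config(admixture = list(mhc_recomb = TRUE, generations = 8L,
                                       mhc_morgans = 2))
  coh <- generate_cohort(cfg)
  fr <- c(coh$mhc_afr_1, coh$mhc_afr_2)
  expect_true(all(fr >= 0 & fr <= 1))
  # fractions are multiples of 1/5 (five locus blocks)
  expect_true(all(abs(fr * 5 - round(fr * 5)) < 1e-9))
  expect_true(any(!fr %in% c(0, 1)))
})

test_that("cohort admixture means track the configured Beta", {
  cfg <- sim_config(admixture = list(cohorts = list(
    reds = list(n = 5000L, afr_mean = 0.497, afr_conc = 5, scd = FALSE))),
    self_id = list(calibration_n = 1000L))
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(coh$q_afr) - 0.497), 0.01)
})

test_that("the SCD cohort is flagged and has elevated African ancestry", {
  cfg <- small_config()
  pools <- generate_pools(cfg)
  scd <- generate_scd_cohort(cfg, pools, n = 417)
  expect_true(all(scd$scd))
  expect_equal(nrow(scd), 417)
  expect_lt(abs(mean(scd$q_afr) - 0.52), 0.02)
  expect_equal(nrow(generate_scd_cohort(cfg, pools, n = 1)), 1)
  # non-SCD cohorts never carry the flag
  coh <- generate_cohort(cfg)
  expect_true(all(!coh$scd[coh$cohort == "general"]))
})

test_that("registry composition, typing fractions and codes follow the
          configuration", {
  cfg <- small_config(registry = list(n = 10000L))
  reg <- generate_registry(cfg)
  comp <- table(reg$self_id) / nrow(reg)
  target <- cfg$registry$composition / sum(cfg$registry$composition)
  for (cat in names(target)) {
    se <- sqrt(target[[cat]] * (1 - target[[cat]]) / nrow(reg))
    expect_lt(abs(comp[[cat]] - target[[cat]]), 3 * se + 1e-9)
  }
  p_c <- mean(!is.na(reg$C_1))
  se_c <- sqrt(0.3 * 0.7 / nrow(reg))
  expect_lt(abs(p_c - cfg$registry$typed_c), 3 * se_c)
  # untyped loci carry no alleles, typed loci carry two
  expect_identical(is.na(reg$C_1), is.na(reg$C_2))
  # low-resolution donors carry one-field names
  low <- reg$typing_resolution == "low"
  expect_true(all(is.na(hla_parse(reg$A_1[low])$field2)))
  # generated codes expand to valid sibling sets
  codes <- hla_codes(reg)
  expect_gt(nrow(codes), 0)
  expect_true(all(lengths(codes$expansion) >= 2))
})

test_that("a single-category composition fills the registry with that
          category", {
  cfg <- small_config(registry = list(
    n = 100L, composition = c(White = 1.0),
    afr_mean = c(White = 0.1)))
  reg <- generate_registry(cfg)
  expect_true(all(reg$self_id == "White"))
})

test_that("registry generation is byte-reproducible", {
  cfg <- small_config()
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_equal(hla_codes(r1)$code_name, hla_codes(r2)$code_name)
})

test_that("African-only individuals show more distinct multilocus
          genotypes than European-only ones", {
  mk <- function(afr_mean) {
    small_config(admixture = list(cohorts = list(
      general = list(n = 300L, afr_mean = afr_mean, afr_conc = 1e5,
                     scd = FALSE),
      scd = NULL)))
  }
  sid <- calibrate_self_id(small_config())
  pools <- generate_pools(small_config())
  geno_string <- function(coh) {
    cols <- paste0(rep(hla_loci, each = 2), "_", 1:2)
    apply(as.matrix(coh[, cols]), 1, paste, collapse = "|")
  }
  afr <- generate_cohort(mk(0.9999), pools, sid)
  eur <- generate_cohort(mk(0.0001), pools, sid)
  expect_gt(length(unique(geno_string(afr))), length(unique(geno_string(eur))))
})

test_that("SNP dosages are binomial draws from ancestry-weighted
          frequencies", {
  cfg <- small_config()
  fr <- generate_snp_freqs(cfg)
  expect_true(all(fr$AFR > 0 & fr$AFR < 1))
  q <- tibble::tibble(q_afr = c(1, 0), q_eur = c(0, 1), q_nat = c(0, 0))
  G <- generate_snp_dosages(q, fr, seed = 7)
  expect_true(all(G %in% 0:2))
  # mean dosage tracks 2 * allele frequency of the source ancestry
  expect_equal(mean(G[1, ]), 2 * mean(fr$AFR), tolerance = 0.05)
  expect_equal(mean(G[2, ]), 2 * mean(fr$EUR), tolerance = 0.05)
})
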