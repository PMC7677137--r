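# Shared fixtures: a scaled-down configuration for fast tests, and a
# tiny hand-built registry exercising typing heterogeneity and codes.

small_config <- function(seed = 20260101L, admixture = list(),
                         self_id = list(), registry = list(),
                         snp = list(), pools = list()) {
  base_adm <- list(cohorts = list(
    general = list(n = 120L, afr_mean = 0.20, afr_conc = 1.0, scd = FALSE),
    scd = list(n = 60L, afr_mean = 0.52, afr_conc = 5.0, scd = TRUE)
  ))
  sim_config(
    seed = seed,
    admixture = utils::modifyList(base_adm, admixture),
    self_id = utils::modifyList(list(calibration_n = 2000L), self_id),
    registry = utils::modifyList(list(n = 500L), registry),
    snp = utils::modifyList(list(n_snps = 400L), snp),
    pools = pools
  )
}

# five donors covering: exact match, low-res typing, untyped C/DQB1,
# NMDP code, unrelated genotype
toy_codes <- function() {
  hla_code_table(list("A*02:AB" = c("A*02:01", "A*02:05")))
}

toy_registry <- function() {
  reg <- tibble::tibble(
    donor_id = sprintf("D%06d", 1:5),
    self_id = c("White", "Mixed", "Black", "White", "Mixed"),
    typing_resolution = c("medium", "medium", "low", "medium", "medium"),
    A_1 = c("A*01:01", "A*02:AB", "A*01", "A*09:01", "A*01:01"),
    A_2 = c("A*02:01", "A*03:02", "A*02", "A*09:02", "A*02:01"),
    B_1 = c("B*05:01", "B*05:01", "B*05", "B*11:01", "B*05:01"),
    B_2 = c("B*06:02", "B*06:02", "B*06", "B*11:02", "B*06:02"),
    C_1 = c("C*03:01", "C*03:01", NA, "C*08:01", "C*03:01"),
    C_2 = c("C*04:01", "C*04:01", NA, "C*08:01", "C*04:01"),
    DRB1_1 = c("DRB1*07:01", "DRB1*07:01", "DRB1*07", "DRB1*09:01",
               "DRB1*07:01"),
    DRB1_2 = c("DRB1*08:01", "DRB1*08:01", "DRB1*08", "DRB1*09:01",
               "DRB1*08:01"),
    DQB1_1 = c("DQB1*02:01", "DQB1*02:01", "DQB1*02", "DQB1*05:01", NA),
    DQB1_2 = c("DQB1*03:01", "DQB1*03:01", "DQB1*03", "DQB1*05:01", NA)
  )
  attr(reg, "codes") <- toy_codes()
  class(reg) <- c("hla_registry", class(reg))
  reg
}

toy_patient <- function() {
  tibble::tibble(
    id = "P00001",
    A_1 = "A*01:01", A_2 = "A*02:01",
    B_1 = "B*05:01", B_2 = "B*06:02",
    C_1 = "C*03:01", C_2 = "C*04:01",
    DRB1_1 = "DRB1*07:01", DRB1_2 = "DRB1*08:01",
    DQB1_1 = "DQB1*02:01", DQB1_2 = "DQB1*03:01"
  )
}

# random two-field genotype tables over a small alphabet, for property
# sweeps (all loci typed, medium resolution)
random_cohort <- function(n, seed, groups = 4, variants = 2) {
  withr::with_seed(seed, {
    out <- tibble::tibble(id = sprintf("R%05d", seq_len(n)))
    for (locus in hla_loci) {
      draw <- function() {
        sprintf("%s*%02d:%02d", locus,
                sample(groups, n, replace = TRUE),
                sample(variants, n, replace = TRUE))
      }
      out[[paste0(locus, "_1")]] <- draw()
      out[[paste0(locus, "_2")]] <- draw()
    }
    out
  })
}

random_registry <- function(n, seed, groups = 4, variants = 2) {
  reg <- random_cohort(n, seed, groups, variants)
  names(reg)[1] <- "donor_id"
  reg$donor_id <- sprintf("D%06d", seq_len(n))
  reg$self_id <- withr::with_seed(seed + 1, {
    sample(c("White", "Mixed", "Black"), n, replace = TRUE)
  })
  reg$typing_resolution <- "medium"
  attr(reg, "codes") <- hla_code_table(list())
  class(reg) <- c("hla_registry", class(reg))
  reg
}
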