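#' Simulation configuration
#'
#' Builds the nested configuration that drives every stochastic stage:
#' ancestry-specific HLA haplotype pools, the admixed patient cohorts
#' (including a sickle-cell-disease cohort with elevated African
#' ancestry), the SNP panel used for supervised ancestry estimation,
#' the self-identification model, and the donor registry with
#' heterogeneous typing.
#'
#' Defaults emulate the Brazilian setting: a merged patient sample that
#' is about two-thirds a general admixed cohort (mean African ancestry
#' 0.20) and one-third an SCD cohort (mean 0.52), so the pooled mean is
#' near 0.31 African / 0.63 European / 0.06 Native American; a registry
#' whose self-identification composition is 54.64% "White", 23.44%
#' "Mixed", 7.17% "Black", 0.46% "Indigenous", 3.31% "Yellow" and
#' 10.97% "NonInformed"; and an African haplotype pool with more
#' distinct haplotypes and higher heterozygosity than the European
#' pool.
#'
#' @param seed Integer seed for the whole run (expanded into
#'   independent per-stage streams by [run_pipeline()]).
#' @param ... Named overrides for any top-level section; each must be a
#'   (partial) list merged over the defaults, e.g.
#'   `sim_config(registry = list(n = 1000))`.
#' @return A list of class `"hla_sim_config"`.
#' @export
sim_config <- function(seed = 20260101L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    pools = list(
      # distinct 5-locus haplotypes per pool; AFR larger and more even
      n_hap_afr = 400L,
      n_hap_eur = 150L,
      # Dirichlet concentration for haplotype frequencies
      hap_alpha_afr = 0.6,
      hap_alpha_eur = 0.5,
      # allele groups (field1) available per locus in the AFR pool
      n_groups = c(A = 15L, B = 20L, C = 10L, DRB1 = 10L, DQB1 = 6L),
      # fraction of each locus' EUR allele groups shared with AFR
      allele_sharing = 1.0,
      # EUR allele-group richness relative to AFR
      eur_group_fraction = 0.55,
      # max protein-level variants per allele group
      variants_afr = 3L,
      variants_eur = 2L,
      # per-locus allele-sampling concentration (skew of allele freqs)
      allele_alpha_afr = 1.2,
      allele_alpha_eur = 0.6
    ),
    admixture = list(
      # cohorts of the merged patient sample
      cohorts = list(
        general = list(n = 1320L, afr_mean = 0.20, afr_conc = 1.0,
                       scd = FALSE),
        scd     = list(n = 680L, afr_mean = 0.52, afr_conc = 5.0,
                       scd = TRUE)
      ),
      nat_mean = 0.061,   # Native American fraction of the non-African rest
      nat_conc = 8.0,
      generations = 8L,         # generations since admixture
      mhc_recomb = FALSE,       # within-MHC recombination switch
      mhc_morgans = 0.027       # genetic length of the A..DQB1 segment
    ),
    self_id = list(
      thresholds = c(white_mixed = 0.20, mixed_black = 0.45),
      target_r2 = 0.64,
      calibration_n = 5000L,
      minor_rates = c(Indigenous = 0.005, Yellow = 0.013,
                      NonInformed = 0.0)
    ),
    snp = list(
      n_snps = 2000L,
      fst = 0.15,              # Balding-Nichols divergence per ancestry
      anc_freq_range = c(0.05, 0.95)
    ),
    registry = list(
      n = 20000L,
      composition = c(White = 0.5464, Mixed = 0.2344, Black = 0.0717,
                      Indigenous = 0.0046, Yellow = 0.0331,
                      NonInformed = 0.1097),
      # self-ID-conditional mean African ancestry of donors
      afr_mean = c(White = 0.10, Mixed = 0.30, Black = 0.55,
                   Indigenous = 0.15, Yellow = 0.08, NonInformed = 0.22),
      afr_conc = 3.0,
      typed_c = 0.30,           # fraction of donors typed at HLA-C
      typed_dqb1 = 0.30,        # fraction typed at HLA-DQB1
      medium_fraction = 0.50,   # donors typed at two-field resolution
      code_fraction = 0.20      # medium donors carrying one NMDP code
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm, call. = FALSE)
    if (nm == "seed") { cfg$seed <- as.integer(over[[nm]]); next }
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    # the cohort collection is replaced wholesale: merging against the
    # default cohorts would silently resurrect them
    if (nm == "admixture" && !is.null(over[[nm]]$cohorts)) {
      cfg$admixture$cohorts <- over[[nm]]$cohorts
    }
  }
  class(cfg) <- "hla_sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$pools
  if (p$n_hap_afr < 2 || p$n_hap_eur < 2) {
    stop("pool sizes must be at least 2", call. = FALSE)
  }
  if (p$n_hap_afr <= p$n_hap_eur) {
    warning("AFR pool is not larger than EUR pool; the diversity ",
            "premise (greater African variability) may not hold")
  }
  if (p$allele_sharing < 0 || p$allele_sharing > 1) {
    stop("allele_sharing must lie in [0, 1]", call. = FALSE)
  }
  comp <- cfg$registry$composition
  # printed compositions may sum to 0.999x; renormalise small drift
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-3) {
    stop("registry composition must be non-negative and sum to 1",
         call. = FALSE)
  }
  probs <- c(cfg$registry$typed_c, cfg$registry$typed_dqb1,
             cfg$registry$medium_fraction, cfg$registry$code_fraction,
             cfg$self_id$minor_rates)
  if (any(probs < 0 | probs > 1)) {
    stop("all configured probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (co in cfg$admixture$cohorts) {
    if (co$afr_mean <= 0 || co$afr_mean >= 1 || co$afr_conc <= 0) {
      stop("cohort Beta parameters out of range", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param path File path for the JSON round trip.
#' @export
write_sim_config <- function(cfg, path) {
  # named atomic vectors must become JSON objects, not bare arrays
  to_jsonable <- function(x) {
    if (is.list(x)) return(lapply(x, to_jsonable))
    if (!is.null(names(x)) && length(x) > 0) return(as.list(x))
    x
  }
  jsonlite::write_json(to_jsonable(unclass(cfg)), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- sim_config(seed = raw$seed)
  for (nm in setdiff(names(raw), "seed")) {
    if (nm %in% names(cfg)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], as_config_list(raw[[nm]]))
  }
  # JSON turns named numeric vectors into lists; restore known vectors
  cfg$pools$n_groups <- unlist(cfg$pools$n_groups)
  cfg$registry$composition <- unlist(cfg$registry$composition)
  cfg$registry$afr_mean <- unlist(cfg$registry$afr_mean)
  cfg$self_id$thresholds <- unlist(cfg$self_id$thresholds)
  cfg$self_id$minor_rates <- unlist(cfg$self_id$minor_rates)
  cfg$snp$anc_freq_range <- unlist(cfg$snp$anc_freq_range)
  class(cfg) <- "hla_sim_config"
  validate_config(cfg)
  cfg
}

as_config_list <- function(x) if (is.list(x)) x else as.list(x)

# Derive an independent per-stage seed below 2^31 from the global seed.
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("pools", "cohort", "registry", "snp", "selfid",
                        "match", "analyze", "scd"))
  if (is.na(idx)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 48271 + idx * 104729) %% 2147483647)
}
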