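# Admixed cohort, SCD cohort and donor registry generators.

rbeta_mean <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

# Draw ancestry proportion vectors (q_afr, q_eur, q_nat).
draw_q <- function(n, afr_mean, afr_conc, adm) {
  q_afr <- rbeta_mean(n, afr_mean, afr_conc)
  nat_rel <- rbeta_mean(n, adm$nat_mean, adm$nat_conc)
  q_nat <- (1 - q_afr) * nat_rel
  tibble::tibble(q_afr = q_afr, q_eur = 1 - q_afr - q_nat, q_nat = q_nat)
}

# Per-haplotype MHC ancestry mosaics and spliced HLA haplotypes.
# Returns a list with mhc_afr (n x 2) and a 5-locus allele matrix per
# haplotype copy. With recombination off each haplotype is a single
# ancestry block (mhc_afr 0 or 1); with it on, ancestry may switch
# between adjacent loci with a per-gap probability derived from the
# number of generations since admixture and the segment's genetic
# length, and alleles are spliced from one AFR and one EUR draw.
draw_haplotypes <- function(n, q_afr, pools, adm) {
  afr <- pools[pools$ancestry == "AFR", ]
  eur <- pools[pools$ancestry == "EUR", ]
  n_loci <- length(hla_loci)
  res <- list()
  for (copy in 1:2) {
    start_afr <- stats::rbinom(n, 1, q_afr)
    if (!isTRUE(adm$mhc_recomb)) {
      mask <- matrix(start_afr, n, n_loci)
    } else {
      p_sw <- 1 - exp(-adm$generations * adm$mhc_morgans / (n_loci - 1))
      mask <- matrix(0L, n, n_loci)
      mask[, 1] <- start_afr
      for (j in 2:n_loci) {
        sw <- stats::rbinom(n, 1, p_sw) == 1
        redraw <- stats::rbinom(n, 1, q_afr)
        mask[, j] <- ifelse(sw, redraw, mask[, j - 1])
      }
    }
    i_afr <- sample.int(nrow(afr), n, replace = TRUE, prob = afr$freq)
    i_eur <- sample.int(nrow(eur), n, replace = TRUE, prob = eur$freq)
    afr_alleles <- as.matrix(afr[i_afr, hla_loci])
    eur_alleles <- as.matrix(eur[i_eur, hla_loci])
    alleles <- ifelse(mask == 1, afr_alleles, eur_alleles)
    dimnames(alleles) <- list(NULL, hla_loci)
    res[[copy]] <- list(mhc_afr = rowMeans(mask), alleles = alleles)
  }
  res
}

#' Calibrate the self-identification model
#'
#' Self-identification is modelled as an ordered-threshold readout of
#' African ancestry: `z = q_afr + noise`, with `z` below the first
#' threshold labelled "White", between the thresholds "Mixed", and
#' above the second "Black". The normal noise scale is tuned by
#' bisection so that the variance in `q_afr` explained by the three
#' categories (computed as in [variance_explained()]) on a calibration
#' sample drawn from the configured admixture distribution hits
#' `target_r2`.
#'
#' @param config A [sim_config()] object; `config$self_id$target_r2`
#'   is used when `target_r2` is `NULL`.
#' @param target_r2 Fraction in (0, 1) to calibrate to.
#' @param cohorts Optional cohort subset (names into
#'   `config$admixture$cohorts`) defining the admixture distribution to
#'   calibrate on; e.g. `"scd"` gives the high-admixture mode, where
#'   the categories capture less of the ancestry variance.
#' @param seed Integer seed.
#' @param tol Bisection tolerance on the achieved R-squared.
#' @return A list of class `"hla_selfid_model"` with elements
#'   `sigma`, `thresholds`, `achieved_r2`, `target_r2`.
#' @export
calibrate_self_id <- function(config = sim_config(), target_r2 = NULL,
                              cohorts = NULL,
                              seed = stage_seed(config$seed, "selfid"),
                              tol = 0.005) {
  if (is.null(target_r2)) target_r2 <- config$self_id$target_r2
  stopifnot(target_r2 > 0, target_r2 < 1)
  thr <- config$self_id$thresholds
  n <- config$self_id$calibration_n
  cos <- config$admixture$cohorts
  if (!is.null(cohorts)) cos <- cos[cohorts]
  q_afr <- withr::with_seed(seed, {
    unlist(lapply(cos, function(co) {
      rbeta_mean(co$n, co$afr_mean, co$afr_conc)
    }))
  })
  q_afr <- rep_len(q_afr, n)

  r2_at <- function(sigma, s) {
    z <- withr::with_seed(s, q_afr + stats::rnorm(length(q_afr), 0, sigma))
    lab <- cut(z, c(-Inf, thr[1], thr[2], Inf),
               labels = c("White", "Mixed", "Black"))
    if (length(unique(lab)) < 2 || stats::var(q_afr) == 0) return(0)
    variance_explained(as.character(lab), q_afr)
  }
  lo <- 1e-4; hi <- 2
  r_lo <- r2_at(lo, seed + 1L)
  r_hi <- r2_at(hi, seed + 1L)
  if (target_r2 > r_lo + tol) {
    stop(sprintf(paste0("target R^2 %.3f unattainable: achievable range ",
                        "is about [%.3f, %.3f] for these thresholds"),
                 target_r2, r_hi, r_lo), call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r_mid <- r2_at(mid, seed + 1L)
    if (abs(r_mid - target_r2) < tol) break
    if (r_mid > target_r2) lo <- mid else hi <- mid
  }
  structure(list(sigma = mid, thresholds = thr, achieved_r2 = r_mid,
                 target_r2 = target_r2),
            class = "hla_selfid_model")
}

# Apply the calibrated self-ID model; minor categories are sprinkled
# in at configured rates, independent of ancestry.
draw_self_id <- function(q_afr, model, minor_rates) {
  n <- length(q_afr)
  z <- q_afr + stats::rnorm(n, 0, model$sigma)
  lab <- as.character(cut(z, c(-Inf, model$thresholds[1],
                               model$thresholds[2], Inf),
                          labels = c("White", "Mixed", "Black")))
  p_minor <- sum(minor_rates)
  if (p_minor > 0) {
    u <- stats::runif(n)
    edges <- cumsum(c(0, minor_rates))
    for (k in seq_along(minor_rates)) {
      hit <- u >= edges[k] & u < edges[k + 1]
      lab[hit] <- names(minor_rates)[k]
    }
  }
  lab
}

#' Generate the admixed patient cohort
#'
#' Draws the merged patient sample from the configured cohorts. Each
#' individual receives an ancestry proportion vector
#' (African/European/Native American), two MHC haplotype ancestry
#' mosaics with the HLA haplotype of each copy drawn from the matching
#' ancestry pool (Native American segments draw from the European pool,
#' which carries no dedicated haplotypes), a five-locus two-field HLA
#' genotype, and a self-identification label from the calibrated
#' threshold model.
#'
#' @param config A [sim_config()] object.
#' @param pools Haplotype pools from [generate_pools()].
#' @param selfid Calibrated model from [calibrate_self_id()]; computed
#'   on the fly when `NULL`.
#' @param seed Integer seed.
#' @return A tibble with one row per individual: `id`, `cohort`,
#'   `self_id`, `scd`, `q_afr`, `q_eur`, `q_nat`, `mhc_afr_1`,
#'   `mhc_afr_2` and typing columns `A_1`, `A_2`, ..., `DQB1_2`.
#' @export
generate_cohort <- function(config = sim_config(), pools = NULL,
                            selfid = NULL,
                            seed = stage_seed(config$seed, "cohort")) {
  if (is.null(pools)) pools <- generate_pools(config)
  if (is.null(selfid)) selfid <- calibrate_self_id(config)
  adm <- config$admixture
  withr::with_seed(seed, {
    parts <- lapply(names(adm$cohorts), function(nm) {
      co <- adm$cohorts[[nm]]
      q <- draw_q(co$n, co$afr_mean, co$afr_conc, adm)
      haps <- draw_haplotypes(co$n, q$q_afr, pools, adm)
      geno <- genotype_tibble(haps)
      tibble::tibble(
        cohort = nm,
        self_id = draw_self_id(q$q_afr, selfid, config$self_id$minor_rates),
        scd = isTRUE(co$scd),
        q,
        mhc_afr_1 = haps[[1]]$mhc_afr,
        mhc_afr_2 = haps[[2]]$mhc_afr
      ) %>% dplyr::bind_cols(geno)
    })
    cohort <- dplyr::bind_rows(parts)
    cohort <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("P%05d", seq_len(nrow(cohort)))), cohort)
  })
  cohort
}

genotype_tibble <- function(haps) {
  out <- list()
  for (locus in hla_loci) {
    out[[paste0(locus, "_1")]] <- haps[[1]]$alleles[, locus]
    out[[paste0(locus, "_2")]] <- haps[[2]]$alleles[, locus]
  }
  tibble::as_tibble(out)
}

#' Generate a sickle-cell-disease patient cohort
#'
#' Individuals flagged `scd = TRUE` with African ancestry drawn from
#' the configured SCD Beta distribution (default mean 0.52, matching
#' the elevated African ancestry of transplant-eligible SCD patients).
#'
#' @inheritParams generate_cohort
#' @param n Number of SCD patients.
#' @return A cohort tibble (see [generate_cohort()]) with
#'   `cohort = "scd"` and `scd = TRUE`.
#' @export
generate_scd_cohort <- function(config = sim_config(), pools = NULL, n = 417L,
                                selfid = NULL,
                                seed = stage_seed(config$seed, "scd")) {
  stopifnot(n >= 1)
  scd_cfg <- config$admixture$cohorts$scd
  if (is.null(scd_cfg)) stop("config has no 'scd' cohort", call. = FALSE)
  # calibrate on the full configured admixture, not the SCD-only subset
  if (is.null(selfid)) selfid <- calibrate_self_id(config)
  cfg <- config
  cfg$admixture$cohorts <- list(scd = utils::modifyList(scd_cfg,
                                                        list(n = as.integer(n))))
  generate_cohort(cfg, pools = pools, selfid = selfid, seed = seed)
}

#' Generate the SNP panel and cohort dosages
#'
#' `generate_snp_freqs()` draws per-ancestry parental allele
#' frequencies for a panel of unlinked biallelic SNPs under a
#' Balding-Nichols model: a shared ancestral frequency per SNP, then
#' ancestry-specific frequencies with divergence controlled by an
#' F_ST-like parameter. `generate_snp_dosages()` draws each
#' individual's genotype dosages binomially from their
#' ancestry-weighted frequency.
#'
#' @param config A [sim_config()] object.
#' @param q Data frame with columns `q_afr`, `q_eur`, `q_nat` (one row
#'   per individual), e.g. a cohort tibble.
#' @param freqs Parental frequency tibble from `generate_snp_freqs()`.
#' @param seed Integer seed.
#' @return `generate_snp_freqs()`: a tibble `snp_id`, `AFR`, `EUR`,
#'   `NAT`. `generate_snp_dosages()`: an integer matrix (individuals x
#'   SNPs) with values in 0:2.
#' @export
generate_snp_freqs <- function(config = sim_config(),
                               seed = stage_seed(config$seed, "snp")) {
  s <- config$snp
  withr::with_seed(seed, {
    p0 <- stats::runif(s$n_snps, s$anc_freq_range[1], s$anc_freq_range[2])
    a <- p0 * (1 - s$fst) / s$fst
    b <- (1 - p0) * (1 - s$fst) / s$fst
    draw <- function() pmin(pmax(stats::rbeta(s$n_snps, a, b), 1e-4), 1 - 1e-4)
    tibble::tibble(snp_id = sprintf("rs%05d", seq_len(s$n_snps)),
                   AFR = draw(), EUR = draw(), NAT = draw())
  })
}

#' @rdname generate_snp_freqs
#' @export
generate_snp_dosages <- function(q, freqs, seed) {
  qm <- as.matrix(q[, c("q_afr", "q_eur", "q_nat")])
  fm <- t(as.matrix(freqs[, c("AFR", "EUR", "NAT")]))
  p <- qm %*% fm
  withr::with_seed(seed, {
    g <- matrix(stats::rbinom(length(p), 2L, as.vector(p)), nrow = nrow(p))
  })
  dimnames(g) <- list(NULL, freqs$snp_id)
  g
}

#' Generate the donor registry
#'
#' Draws donors with the configured self-identification composition
#' (default: the printed composition of the Brazilian registry), each
#' donor's HLA genotype produced by the same admixture mechanism as the
#' cohort but with ancestry drawn from a self-ID-conditional Beta.
#' Typing is heterogeneous: all donors are typed at HLA-A, -B and
#' -DRB1; HLA-C and -DQB1 are typed with configured probabilities; each
#' donor is typed at low (one-field) or medium (two-field) resolution;
#' and a configured fraction of medium-resolution donors carry one
#' NMDP-style multiple-allele code in place of a fully resolved allele.
#'
#' @inheritParams generate_cohort
#' @return A tibble of class `"hla_registry"` with columns `donor_id`,
#'   `self_id`, `typing_resolution` and typing columns (`NA` = untyped
#'   locus), with the generated NMDP code table attached as attribute
#'   `"codes"` (see [hla_codes()]).
#' @export
generate_registry <- function(config = sim_config(), pools = NULL,
                              seed = stage_seed(config$seed, "registry")) {
  if (is.null(pools)) pools <- generate_pools(config)
  r <- config$registry
  adm <- config$admixture
  n <- r$n
  withr::with_seed(seed, {
    self_id <- sample(names(r$composition), n, replace = TRUE,
                      prob = r$composition / sum(r$composition))
    q_afr <- rbeta_mean(n, r$afr_mean[self_id], r$afr_conc)
    haps <- draw_haplotypes(n, q_afr, pools, adm)
    geno <- genotype_tibble(haps)
    donors <- tibble::tibble(
      donor_id = sprintf("D%06d", seq_len(n)),
      self_id = self_id,
      typing_resolution = ifelse(stats::runif(n) < r$medium_fraction,
                                 "medium", "low")
    ) %>% dplyr::bind_cols(geno)

    # typing completeness: C and DQB1 only for configured subsets
    untype <- function(cols, keep_p) {
      drop <- stats::runif(n) >= keep_p
      for (cl in cols) donors[[cl]][drop] <<- NA_character_
      drop
    }
    untype(c("C_1", "C_2"), r$typed_c)
    untype(c("DQB1_1", "DQB1_2"), r$typed_dqb1)

    # low-resolution donors carry one-field names
    low <- donors$typing_resolution == "low"
    for (cl in paste0(rep(hla_loci, each = 2), "_", 1:2)) {
      has <- low & !is.na(donors[[cl]])
      donors[[cl]][has] <- hla_truncate(donors[[cl]][has], "low")
    }

    # NMDP codes: replace one typed allele of some medium donors with a
    # code expanding to the true allele plus sibling variants of the
    # same allele group
    codes <- list()
    med_idx <- which(!low & stats::runif(n) < r$code_fraction)
    universe <- pool_allele_universe(pools)
    label_for <- code_labeller()
    for (i in med_idx) {
      slots <- paste0(rep(hla_loci, each = 2), "_", 1:2)
      slots <- slots[!is.na(unlist(donors[i, slots]))]
      slot <- sample(slots, 1)
      true_allele <- donors[[slot]][i]
      sibs <- sibling_variants(true_allele, universe)
      if (length(sibs) < 2) next
      members <- sort(unique(c(true_allele,
                               sample(sibs, min(length(sibs), 3)))))
      key <- paste(members, collapse = ";")
      if (is.null(codes[[key]])) {
        p1 <- hla_parse(true_allele)
        codes[[key]] <- sprintf("%s*%02d:%s", p1$locus, p1$field1,
                                label_for(key))
      }
      donors[[slot]][i] <- codes[[key]]
    }
    code_tab <- hla_code_table(stats::setNames(
      lapply(names(codes), function(k) strsplit(k, ";", fixed = TRUE)[[1]]),
      unlist(codes)))
  })
  attr(donors, "codes") <- code_tab
  class(donors) <- c("hla_registry", class(donors))
  donors
}

# all two-field alleles present in either pool, by locus and group
pool_allele_universe <- function(pools) {
  long <- tidyr::pivot_longer(tibble::as_tibble(pools),
                              dplyr::all_of(hla_loci),
                              names_to = "locus", values_to = "allele")
  sort(unique(long$allele))
}

sibling_variants <- function(allele, universe) {
  pre <- paste0(hla_truncate(allele, "low"), ":")
  universe[startsWith(universe, pre) & universe != allele]
}

# deterministic two-letter code labels AA, AB, AC, ... per expansion set
code_labeller <- function() {
  counter <- 0L
  seen <- new.env(parent = emptyenv())
  function(key) {
    if (!is.null(seen[[key]])) return(seen[[key]])
    counter <<- counter + 1L
    lab <- paste0(LETTERS[(counter - 1L) %/% 26L + 1L],
                  LETTERS[(counter - 1L) %% 26L + 1L])
    seen[[key]] <- lab
    lab
  }
}

#' Extract the NMDP code table attached to a registry
#'
#' @param registry A registry tibble from [generate_registry()] or
#'   [read_registry()].
#' @return A code table tibble (see [hla_code_table()]).
#' @export
hla_codes <- function(registry) {
  codes <- attr(registry, "codes")
  if (is.null(codes)) hla_code_table(list()) else codes
}
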