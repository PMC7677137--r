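# Ancestry-specific HLA haplotype pools.

rdirichlet1 <- function(alpha_n, alpha) {
  g <- stats::rgamma(alpha_n, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, alpha_n)
  g / sum(g)
}

# Per-locus allele universes for both pools. EUR allele groups are a
# subset of (or, with sharing < 1, partly disjoint from) the AFR
# groups; EUR carries fewer protein-level variants per group.
build_allele_universe <- function(pools_cfg) {
  out <- list()
  for (locus in hla_loci) {
    ng <- pools_cfg$n_groups[[locus]]
    afr_groups <- seq_len(ng)
    nv_afr <- sample(pools_cfg$variants_afr, ng, replace = TRUE)
    n_eur <- max(1L, ceiling(pools_cfg$eur_group_fraction * ng))
    n_shared <- round(pools_cfg$allele_sharing * n_eur)
    shared <- if (n_shared > 0) sort(sample(afr_groups, n_shared)) else integer(0)
    novel <- if (n_eur - n_shared > 0) ng + seq_len(n_eur - n_shared) else integer(0)
    eur_groups <- c(shared, novel)
    nv_eur_new <- sample(pools_cfg$variants_eur, length(novel), replace = TRUE)

    mk <- function(groups, nvar) {
      tibble::tibble(
        group = rep(groups, nvar),
        variant = as.integer(unlist(lapply(nvar, seq_len), use.names = FALSE))
      ) %>%
        dplyr::mutate(allele = sprintf("%s*%02d:%02d", locus, .data$group,
                                       .data$variant))
    }
    afr_tab <- mk(afr_groups, nv_afr)
    # shared EUR groups reuse the AFR group's variants (capped), so
    # low-resolution identity across pools is preserved
    nv_eur_sh <- pmin(nv_afr[shared], pools_cfg$variants_eur)
    eur_tab <- rbind(mk(shared, nv_eur_sh), mk(novel, nv_eur_new))
    out[[locus]] <- list(AFR = afr_tab, EUR = eur_tab)
  }
  out
}

#' Generate ancestry-specific HLA haplotype pools
#'
#' Draws the African (AFR) and European (EUR) five-locus haplotype
#' pools used by the cohort and registry generators. The AFR pool has
#' more distinct haplotypes, more allele groups per locus and a more
#' even frequency distribution, embodying the higher HLA diversity of
#' African populations that drives lower match probabilities.
#'
#' Each pool is built by (i) drawing a per-locus allele frequency
#' distribution from a Dirichlet over the pool's allele universe,
#' (ii) assembling distinct five-locus haplotypes from those allele
#' distributions, and (iii) drawing haplotype frequencies from a
#' Dirichlet whose concentration controls how skewed the pool is.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to the config's pools stream.
#' @return A tibble of class `"hla_pools"` with columns `ancestry`
#'   (`"AFR"`/`"EUR"`), `hap_id`, one column per locus (two-field
#'   allele names) and `freq` (frequencies sum to 1 within ancestry).
#' @export
generate_pools <- function(config = sim_config(),
                           seed = stage_seed(config$seed, "pools")) {
  p <- config$pools
  withr::with_seed(seed, {
    universe <- build_allele_universe(p)
    one_pool <- function(anc, n_hap, hap_alpha, allele_alpha) {
      allele_freqs <- lapply(hla_loci, function(locus) {
        tab <- universe[[locus]][[anc]]
        stats::setNames(rdirichlet1(nrow(tab), allele_alpha), tab$allele)
      })
      names(allele_freqs) <- hla_loci
      # rejection-style assembly of distinct haplotypes
      haps <- character(0)
      draw <- function(m) {
        cols <- vapply(hla_loci, function(locus) {
          f <- allele_freqs[[locus]]
          sample(names(f), m, replace = TRUE, prob = f)
        }, character(m))
        apply(matrix(cols, nrow = m), 1, paste, collapse = "|")
      }
      for (i in 1:60) {
        haps <- unique(c(haps, draw(2L * n_hap)))
        if (length(haps) >= n_hap) break
      }
      if (length(haps) < n_hap) {
        stop("could not assemble ", n_hap, " distinct haplotypes; ",
             "increase allele universe or lower pool size", call. = FALSE)
      }
      haps <- haps[seq_len(n_hap)]
      parts <- do.call(rbind, strsplit(haps, "|", fixed = TRUE))
      colnames(parts) <- hla_loci
      tibble::tibble(
        ancestry = anc,
        hap_id = sprintf("%s_H%04d", anc, seq_len(n_hap)),
        tibble::as_tibble(parts),
        freq = rdirichlet1(n_hap, hap_alpha)
      )
    }
    pools <- dplyr::bind_rows(
      one_pool("AFR", p$n_hap_afr, p$hap_alpha_afr, p$allele_alpha_afr),
      one_pool("EUR", p$n_hap_eur, p$hap_alpha_eur, p$allele_alpha_eur)
    )
  })
  class(pools) <- c("hla_pools", class(pools))
  pools
}

#' Expected heterozygosity per locus of a haplotype pool
#'
#' Computes `1 - sum(p_a^2)` per locus and ancestry from the marginal
#' allele frequencies implied by the haplotype frequencies. Under the
#' default configuration the AFR pool has higher heterozygosity than
#' the EUR pool at every locus.
#'
#' @param pools A pool tibble from [generate_pools()].
#' @param resolution Compare alleles at `"medium"` (two-field, default)
#'   or `"low"` (allele-group) resolution.
#' @return A tibble with columns `ancestry`, `locus`, `heterozygosity`.
#' @export
pool_heterozygosity <- function(pools, resolution = "medium") {
  pools %>%
    tidyr::pivot_longer(dplyr::all_of(hla_loci), names_to = "locus",
                        values_to = "allele") %>%
    dplyr::mutate(allele = hla_truncate(.data$allele, resolution)) %>%
    dplyr::group_by(.data$ancestry, .data$locus, .data$allele) %>%
    dplyr::summarise(p = sum(.data$freq), .groups = "drop_last") %>%
    dplyr::summarise(heterozygosity = 1 - sum(.data$p^2), .groups = "drop")
}
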