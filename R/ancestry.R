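# Supervised ancestry estimation and ancestry-based group assignment.

#' Supervised maximum-likelihood ancestry estimation
#'
#' Estimates per-individual ancestry proportions from SNP dosages given
#' fixed parental allele frequencies: the supervised special case of
#' the ADMIXTURE-style model, in which each genotype dosage `g_j` is
#' binomial with success probability `sum_k q_k f_kj`. The simplex-
#' constrained maximum-likelihood estimate is found by EM, whose
#' updates never decrease the log-likelihood; iteration stops when the
#' per-individual log-likelihood gain drops below `tol` or after
#' `max_iter` iterations. Missing dosages are skipped.
#'
#' `estimate_ancestry()` handles one individual;
#' `estimate_ancestry_all()` runs the same EM for a whole dosage
#' matrix at once.
#'
#' @param dosages Integer vector of genotype dosages in `0:2`
#'   (`NA` = missing), one per SNP.
#' @param freqs Parental frequency tibble (`snp_id`, one column per
#'   ancestry) as from [generate_snp_freqs()], or a numeric matrix
#'   (SNPs x ancestries). Frequencies are clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @param tol Convergence threshold on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @return `estimate_ancestry()`: a list of class
#'   `"hla_ancestry_fit"` with `q_hat` (named proportions summing
#'   to 1), `loglik`, `iterations`, `converged`.
#'   `estimate_ancestry_all()`: a tibble with one row per individual:
#'   `q_afr_hat`, `q_eur_hat`, `q_nat_hat`, `loglik`, `iterations`,
#'   `converged`.
#' @examples
#' cfg <- sim_config(snp = list(n_snps = 200))
#' fr <- generate_snp_freqs(cfg, seed = 1)
#' q <- data.frame(q_afr = 1, q_eur = 0, q_nat = 0)
#' g <- generate_snp_dosages(q, fr, seed = 2)
#' estimate_ancestry(g[1, ], fr)$q_hat
#' @export
estimate_ancestry <- function(dosages, freqs, tol = 1e-7, max_iter = 1000L) {
  fit <- estimate_ancestry_all(matrix(dosages, nrow = 1), freqs,
                               tol = tol, max_iter = max_iter)
  anc <- colnames(freq_matrix(freqs))
  structure(list(
    q_hat = stats::setNames(as.numeric(fit[1, paste0("q_", tolower(anc),
                                                     "_hat")]), anc),
    loglik = fit$loglik[1],
    iterations = fit$iterations[1],
    converged = fit$converged[1]
  ), class = "hla_ancestry_fit")
}

freq_matrix <- function(freqs) {
  if (is.matrix(freqs)) {
    f <- freqs
    if (is.null(colnames(f))) colnames(f) <- c("AFR", "EUR", "NAT")[seq_len(ncol(f))]
  } else {
    anc <- setdiff(names(freqs), "snp_id")
    f <- as.matrix(freqs[, anc])
  }
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' @rdname estimate_ancestry
#' @param G Dosage matrix (individuals x SNPs).
#' @param trace Record the per-iteration log-likelihood history
#'   (attached as attribute `"trace"`, a list of numeric vectors).
#' @export
estimate_ancestry_all <- function(G, freqs, tol = 1e-7, max_iter = 1000L,
                                  trace = FALSE) {
  G <- as.matrix(G)
  if (!all(is.na(G) | (is.finite(G) & G %in% 0:2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  F <- freq_matrix(freqs)               # J x K
  if (nrow(F) != ncol(G)) stop("dosage/frequency dimension mismatch",
                               call. = FALSE)
  K <- ncol(F)
  if (any(rowSums(!is.na(G)) == 0)) {
    stop("an individual has no observed SNPs", call. = FALSE)
  }
  # likelihood is flat when all ancestries share the same frequencies
  flat <- all(abs(F - F[, 1]) < 1e-12)

  storage.mode(G) <- "integer"
  fit <- .em_ancestry(G, F, tol, as.integer(max_iter), isTRUE(trace))
  out <- tibble::tibble(
    !!!stats::setNames(lapply(seq_len(K), function(k) fit$Q[, k]),
                       paste0("q_", tolower(colnames(F)), "_hat")),
    loglik = fit$loglik,
    iterations = fit$iters,
    converged = if (flat) rep(FALSE, nrow(G)) else fit$iters < max_iter
  )
  if (isTRUE(trace)) attr(out, "trace") <- fit$trace
  out
}

#' @export
print.hla_ancestry_fit <- function(x, ...) {
  cat("Supervised ancestry estimate (EM)\n")
  cat(sprintf("  q_hat: %s\n",
              paste(sprintf("%s = %.4f", names(x$q_hat), x$q_hat),
                    collapse = ", ")))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hla_ancestry_fit <- function(x, ...) {
  tibble::tibble(ancestry = names(x$q_hat), estimate = unname(x$q_hat))
}

#' @exportS3Method generics::glance
glance.hla_ancestry_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged)
}

#' Quartiles of African ancestry
#'
#' Rank-based quartiles of a sample of African ancestry proportions,
#' Q1 the least African. Ties are broken by stable input order, so the
#' four groups have (near-)equal sizes even for degenerate samples; the
#' realized boundaries (the ancestry values at the group edges) are
#' attached as attribute `"boundaries"`, with `"degenerate"` flagging
#' collapsed boundaries.
#'
#' @param q_afr Numeric vector of African ancestry proportions
#'   (length >= 4).
#' @return A factor with levels `Q1`-`Q4` and attributes `boundaries`
#'   and `degenerate`.
#' @export
assign_quartiles <- function(q_afr) {
  n <- length(q_afr)
  if (n < 4) stop("need at least 4 values for quartiles", call. = FALSE)
  r <- rank(q_afr, ties.method = "first")
  idx <- ceiling(4 * r / n)
  f <- factor(paste0("Q", idx), levels = paste0("Q", 1:4))
  bounds <- vapply(1:3, function(k) max(q_afr[idx <= k]), numeric(1))
  attr(f, "boundaries") <- stats::setNames(bounds, c("Q1|Q2", "Q2|Q3", "Q3|Q4"))
  attr(f, "degenerate") <- any(duplicated(bounds)) ||
    any(bounds %in% range(q_afr)[1]) && stats::var(q_afr) == 0
  f
}

#' African MHC dosage class
#'
#' Number of chromosomes whose MHC segment is African (0, 1 or 2):
#' each haplotype's African fraction is rounded to the nearest integer
#' (0.5 rounds up, toward African), then the two are summed. Mixed
#' fractions arise only when within-MHC recombination is enabled.
#'
#' @param mhc_afr_1,mhc_afr_2 African fraction of the MHC segment on
#'   each chromosome, in `[0, 1]`.
#' @return Integer vector with values in `0:2`.
#' @examples
#' mhc_dosage(1, 0)      # 1
#' mhc_dosage(0.8, 0.1)  # 1
#' @export
mhc_dosage <- function(mhc_afr_1, mhc_afr_2) {
  v <- c(mhc_afr_1, mhc_afr_2)
  if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
    stop("MHC African fractions must lie in [0, 1]", call. = FALSE)
  }
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  round_half_up(mhc_afr_1) + round_half_up(mhc_afr_2)
}

#' Variance in a quantitative trait explained by group labels
#'
#' One-way analysis-of-variance R-squared: `1 - SS_within / SS_total`
#' of `values` partitioned by `labels` (identical to the R-squared of a
#' regression on category indicators). Used to quantify how much of
#' the variation in African ancestry the self-identification
#' categories capture.
#'
#' @param labels Category label per individual (at least two distinct
#'   categories).
#' @param values Numeric vector, same length.
#' @return A fraction in `[0, 1]`.
#' @export
variance_explained <- function(labels, values) {
  stopifnot(length(labels) == length(values))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("R^2 undefined with a single category", call. = FALSE)
  }
  ss_total <- sum((values - mean(values))^2)
  if (ss_total == 0) stop("values have zero variance", call. = FALSE)
  ss_within <- sum(tapply(values, labels, function(v) {
    sum((v - mean(v))^2)
  }))
  1 - ss_within / ss_total
}

#' Attach ancestry-based group assignments to a cohort
#'
#' Convenience wrapper adding `quartile` (African-ancestry quartile,
#' from [assign_quartiles()]) and `mhc_dosage` (from [mhc_dosage()])
#' columns to a cohort tibble.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return The cohort with `quartile` and `mhc_dosage` columns added.
#' @export
assign_groups <- function(cohort) {
  cohort %>%
    dplyr::mutate(
      quartile = assign_quartiles(.data$q_afr),
      mhc_dosage = mhc_dosage(.data$mhc_afr_1, .data$mhc_afr_2)
    )
}
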