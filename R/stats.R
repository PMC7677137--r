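# Match statistics: grouped rates, odds ratios, matched-subsample
# percent decreases, donor composition, rank and proportion tests, and
# the sibling match probability.

#' Match rates by group
#'
#' Per-group proportion of patients with at least one matching donor.
#'
#' @param match_tbl Match table from [batch_match()], filtered to one
#'   search specification (or pass `loci_set`/`resolution`/
#'   `max_mismatch` to filter here).
#' @param assignments Tibble with `id` and the grouping column (e.g. a
#'   cohort from [assign_groups()]).
#' @param grouping Name of the grouping column (`"self_id"`,
#'   `"quartile"`, `"mhc_dosage"`, `"scd"`, ...).
#' @param loci_set,resolution,max_mismatch Optional filters applied to
#'   `match_tbl`.
#' @return A tibble of class `"hla_grouped_rates"`: `group`, `n`,
#'   `n_with_match`, `rate`.
#' @export
grouped_match_rates <- function(match_tbl, assignments, grouping,
                                loci_set = NULL, resolution = NULL,
                                max_mismatch = NULL) {
  if (!is.null(loci_set)) {
    match_tbl <- dplyr::filter(match_tbl, .data$loci_set == .env$loci_set)
  }
  if (!is.null(resolution)) {
    match_tbl <- dplyr::filter(match_tbl, .data$resolution == .env$resolution)
  }
  if (!is.null(max_mismatch)) {
    match_tbl <- dplyr::filter(match_tbl,
                               .data$max_mismatch == .env$max_mismatch)
  }
  joined <- match_tbl %>%
    dplyr::inner_join(
      assignments %>% dplyr::select("id", dplyr::all_of(grouping)),
      by = c(patient_id = "id"))
  if (anyNA(joined[[grouping]])) {
    stop("every patient needs a group assignment under '", grouping, "'",
         call. = FALSE)
  }
  out <- joined %>%
    dplyr::group_by(group = as.character(.data[[grouping]])) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_with_match = sum(.data$n_matches >= 1, na.rm = TRUE),
                     rate = .data$n_with_match / .data$n,
                     .groups = "drop") %>%
    dplyr::mutate(grouping = grouping, .before = 1)
  class(out) <- c("hla_grouped_rates", class(out))
  out
}

#' Odds ratio for finding at least one match
#'
#' Closed-form odds ratio from the 2x2 table of outcome by group, with
#' a Woolf (log-normal) 95% confidence interval and a Wald p-value,
#' cross-checked against a univariate logistic regression fitted by
#' iteratively reweighted least squares (`stats::glm`). When a table
#' cell is zero the Haldane-Anscombe 0.5 correction is applied and the
#' logistic cross-check is skipped (flagged in the result).
#'
#' @param outcome Logical (or 0/1) vector: found at least one match.
#' @param group Logical (or two-level) vector: exposure indicator; the
#'   odds ratio is for `TRUE` (or the second level) versus the
#'   reference.
#' @param conf_level Confidence level for the Woolf interval.
#' @return A list of class `"hla_or"` with `or`, `conf_low`,
#'   `conf_high`, `p_value`, `table`, `logistic_or`, `corrected`.
#' @export
odds_ratio <- function(outcome, group, conf_level = 0.95) {
  outcome <- as.logical(outcome)
  if (!is.logical(group)) {
    lev <- sort(unique(as.character(group)))
    if (length(lev) != 2) stop("group must have exactly two levels",
                               call. = FALSE)
    group <- as.character(group) == lev[2]
  }
  if (length(unique(outcome)) < 2) {
    stop("both outcome levels must be present", call. = FALSE)
  }
  a <- sum(group & outcome)      # exposed, matched
  b <- sum(group & !outcome)
  c_ <- sum(!group & outcome)    # reference, matched
  d <- sum(!group & !outcome)
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  log_or <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  logistic_or <- NA_real_
  if (!corrected) {
    fit <- stats::glm(outcome ~ group, family = stats::binomial())
    logistic_or <- exp(stats::coef(fit)[["groupTRUE"]])
  }
  structure(list(
    or = exp(log_or),
    conf_low = exp(log_or - z * se),
    conf_high = exp(log_or + z * se),
    p_value = 2 * stats::pnorm(-abs(log_or / se)),
    table = matrix(c(a, b, c_, d), 2, 2,
                   dimnames = list(c("matched", "unmatched"),
                                   c("exposed", "reference"))),
    logistic_or = logistic_or,
    corrected = corrected
  ), class = "hla_or")
}

#' @export
print.hla_or <- function(x, ...) {
  cat(sprintf("Odds ratio %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
              x$or, x$conf_low, x$conf_high, x$p_value,
              if (x$corrected) " [0.5 correction applied]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hla_or <- function(x, ...) {
  tibble::tibble(estimate = x$or, conf.low = x$conf_low,
                 conf.high = x$conf_high, p.value = x$p_value,
                 logistic_estimate = x$logistic_or, corrected = x$corrected)
}

#' Percent decrease in match rates between two groups
#'
#' The relative drop in the chance of finding at least one match,
#' `100 * (r_ref - r_cmp) / r_ref`, reported rounded to an integer
#' percent (half away from zero, the convention used for printed
#' percent decreases). When `matched_sizes = TRUE` the inputs must be
#' the raw per-patient outcome vectors; the larger group is randomly
#' subsampled to the smaller group's size, the rates averaged over
#' `reps` subsamples before taking the ratio — the matched-size
#' protocol that makes groups of unequal size directly comparable.
#'
#' @param ref Reference group: rate in `[0, 1]` (or percentage in
#'   `(1, 100]`) or, for matched sizes, a logical outcome vector.
#' @param cmp Comparison group, same form as `ref`.
#' @param matched_sizes Subsample to equal group sizes first.
#' @param reps Number of subsample repetitions.
#' @param seed Seed for the subsampling stream.
#' @return A list of class `"hla_pct_decrease"` with `percent`
#'   (integer), `raw` (unrounded), `rate_ref`, `rate_cmp`.
#' @examples
#' percent_decrease(91.1, 82.9)$percent  # 9
#' percent_decrease(16.9, 7.3)$percent   # 57
#' @export
percent_decrease <- function(ref, cmp, matched_sizes = FALSE, reps = 200L,
                             seed = NULL) {
  as_rate <- function(x) if (length(x) == 1 && x > 1) x / 100 else x
  if (matched_sizes) {
    if (length(ref) < 2 || length(cmp) < 2) {
      stop("matched_sizes needs per-patient outcome vectors", call. = FALSE)
    }
    ref <- as.logical(ref); cmp <- as.logical(cmp)
    n <- min(length(ref), length(cmp))
    sub_rate <- function(x) {
      if (length(x) == n) return(rep(mean(x), reps))
      vapply(seq_len(reps), function(i) mean(sample(x, n)), numeric(1))
    }
    run <- function() {
      r_ref <- mean(sub_rate(ref))
      r_cmp <- mean(sub_rate(cmp))
      list(r_ref = r_ref, r_cmp = r_cmp)
    }
    rates <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    r_ref <- rates$r_ref; r_cmp <- rates$r_cmp
  } else {
    if (length(ref) > 1) ref <- mean(as.logical(ref))
    if (length(cmp) > 1) cmp <- mean(as.logical(cmp))
    r_ref <- as_rate(ref); r_cmp <- as_rate(cmp)
  }
  if (r_ref <= 0) stop("reference rate must be positive", call. = FALSE)
  raw <- 100 * (r_ref - r_cmp) / r_ref
  structure(list(percent = round_half_away(raw), raw = raw,
                 rate_ref = r_ref, rate_cmp = r_cmp),
            class = "hla_pct_decrease")
}

# round half away from zero (printed-percentage convention)
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @export
print.hla_pct_decrease <- function(x, ...) {
  cat(sprintf("Percent decrease: %d%% (%.2f%% -> %.2f%%)\n",
              as.integer(x$percent), 100 * x$rate_ref, 100 * x$rate_cmp))
  invisible(x)
}

#' Donor self-identification composition per patient group
#'
#' For every patient with at least one match, the frequency of each
#' donor self-identification category among that patient's matched
#' donors; per patient group, the unweighted mean of those per-patient
#' frequency vectors (the "average of individual averages", which
#' weights every patient equally rather than pooling donors).
#'
#' @param match_tbl Match table from
#'   `batch_match(..., keep_donor_ids = TRUE)`, filtered to one search
#'   specification.
#' @param registry Registry tibble (for donor `self_id`).
#' @param assignments Tibble with `id` and the grouping column.
#' @param grouping Name of the patient grouping column.
#' @return A tibble: `group`, `donor_self_id`, `share`; shares sum to
#'   1 within each group with at least one matched patient.
#' @export
donor_composition <- function(match_tbl, registry, assignments, grouping) {
  if (!"donor_ids" %in% names(match_tbl)) {
    stop("match table lacks donor_ids; rerun batch_match with ",
         "keep_donor_ids = TRUE", call. = FALSE)
  }
  donor_cat <- stats::setNames(registry$self_id, registry$donor_id)
  cats <- sort(unique(registry$self_id))
  matched <- match_tbl %>% dplyr::filter(.data$n_matches >= 1)
  per_patient <- purrr::map(matched$donor_ids, function(ids) {
    tab <- table(factor(donor_cat[ids], levels = cats))
    as.numeric(tab) / length(ids)
  })
  freq <- do.call(rbind, per_patient)
  colnames(freq) <- cats
  tibble::tibble(patient_id = matched$patient_id,
                 tibble::as_tibble(freq)) %>%
    dplyr::inner_join(
      assignments %>% dplyr::select("id", dplyr::all_of(grouping)),
      by = c(patient_id = "id")) %>%
    tidyr::pivot_longer(dplyr::all_of(cats), names_to = "donor_self_id",
                        values_to = "share") %>%
    dplyr::group_by(group = as.character(.data[[grouping]]),
                    .data$donor_self_id) %>%
    dplyr::summarise(share = mean(.data$share), .groups = "drop") %>%
    dplyr::mutate(grouping = grouping, .before = 1)
}

#' Mann-Whitney U test on donor counts
#'
#' Two-sided Mann-Whitney U comparing the number of potential donors
#' between two groups of patients, computed only over patients with at
#' least one match. Uses the normal approximation with tie correction
#' (via `stats::wilcox.test`) for samples of 20 or more, the exact
#' distribution below that.
#'
#' @param counts_a,counts_b Integer vectors of per-patient donor
#'   counts (patients with at least one match).
#' @return A tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
donor_count_test <- function(counts_a, counts_b) {
  stopifnot(all(counts_a >= 1), all(counts_b >= 1))
  exact <- min(length(counts_a), length(counts_b)) < 20
  wt <- suppressWarnings(stats::wilcox.test(counts_a, counts_b,
                                            exact = exact, correct = FALSE))
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(counts_a), n_b = length(counts_b),
                 method = if (exact) "exact" else "normal approximation")
}

#' Two-proportion z test
#'
#' Pooled-variance two-proportion z statistic with a two-sided normal
#' p-value, as used to compare the match rate of transplant-eligible
#' SCD patients against non-SCD individuals.
#'
#' @param p1,p2 Group proportions in `[0, 1]`.
#' @param n1,n2 Group sizes.
#' @return A tibble: `z`, `p_value`.
#' @examples
#' two_prop_ztest(0.081, 417, 0.144, 5334)
#' @export
two_prop_ztest <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  pool <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Probability of an HLA-genoidentical sibling
#'
#' Under Mendelian inheritance each sibling has probability 1/4 of
#' carrying the same two parental HLA haplotypes as the patient, so
#' with `k` siblings the probability that at least one is
#' genoidentical is `1 - (3/4)^k`.
#'
#' @param k Non-negative integer number of siblings (vectorised).
#' @return Probability in `[0, 1]`.
#' @examples
#' sibling_match_prob(1)  # 0.25
#' sibling_match_prob(3)  # 0.578125
#' @export
sibling_match_prob <- function(k) {
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  1 - (3 / 4)^k
}
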