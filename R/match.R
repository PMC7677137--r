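# Registry search: indexed multilocus HLA matching with a naive-scan
# reference implementation.

#' Search specification
#'
#' A search is defined by the loci set (`"6/6"` = A, B, DRB1; `"8/8"`
#' adds C; `"10/10"` adds DQB1), the comparison resolution, and the
#' mismatch allowance (0 for full matching; 1 allows a mismatch at a
#' single allele anywhere across the loci set, i.e. 5/6, 7/8, 9/10).
#'
#' @param loci_set `"6/6"`, `"8/8"` or `"10/10"`.
#' @param resolution `"low"` or `"medium"`.
#' @param max_mismatch 0 or 1 (total mismatched alleles allowed).
#' @return A list of class `"hla_search_spec"`.
#' @export
search_spec <- function(loci_set = c("6/6", "8/8", "10/10"),
                        resolution = c("low", "medium"),
                        max_mismatch = 0L) {
  loci_set <- match.arg(loci_set)
  resolution <- match.arg(resolution)
  max_mismatch <- as.integer(max_mismatch)
  stopifnot(max_mismatch %in% 0:1)
  structure(list(loci_set = loci_set, resolution = resolution,
                 max_mismatch = max_mismatch, loci = loci_for_set(loci_set)),
            class = "hla_search_spec")
}

#' All twelve standard search specifications
#'
#' The cross of three loci sets, two resolutions and mismatch
#' allowances 0 and 1.
#'
#' @return A list of [search_spec()] objects.
#' @export
all_search_specs <- function() {
  grid <- expand.grid(loci_set = c("6/6", "8/8", "10/10"),
                      resolution = c("low", "medium"),
                      max_mismatch = 0:1, stringsAsFactors = FALSE)
  purrr::pmap(grid, search_spec)
}

# Per-entry match keys for a vector of donor entries at one locus:
# every truncated name under which the entry can match one patient
# allele. Codes expand to their members; one-field entries yield no
# keys at medium resolution (insufficient-resolution rule).
donor_entry_keys <- function(entries, resolution, codes) {
  n <- length(entries)
  out <- rep(list(character(0)), n)
  live <- which(!is.na(entries))
  if (length(live) == 0) return(out)
  p <- hla_parse(entries[live])
  if (resolution == "low") {
    out[live] <- as.list(paste0(p$locus, "*", sprintf("%02d", p$field1)))
    return(out)
  }
  res <- rep(list(character(0)), length(live))
  isc <- which(!is.na(p$code))
  if (length(isc) > 0) {
    hit <- match(hla_format(p[isc, , drop = FALSE]), codes$code_name)
    if (any(is.na(hit))) {
      stop("unknown NMDP code: '", entries[live][isc][is.na(hit)][1], "'",
           call. = FALSE)
    }
    res[isc] <- codes$expansion[hit]
  }
  two <- which(is.na(p$code) & !is.na(p$field2))
  res[two] <- as.list(sprintf("%s*%02d:%02d", p$locus[two], p$field1[two],
                              p$field2[two]))
  out[live] <- res
  out
}

# Vectorized patient-side keys for one locus of a cohort table.
patient_keys <- function(a1, a2, resolution) {
  k1 <- hla_truncate(a1, resolution)
  k2 <- hla_truncate(a2, resolution)
  list(k1 = k1, k2 = k2,
       geno = ifelse(is.na(k1) | is.na(k2), NA_character_,
                     paste(pmin(k1, k2), pmax(k1, k2), sep = "/")))
}

#' Build a registry match index
#'
#' Precomputes, for each locus and resolution, (i) a genotype-key
#' lookup giving the donors with zero mismatches at that locus and
#' (ii) an allele-key lookup giving the donors with at least one
#' compatible allele (mismatch at most one). Donors carrying NMDP
#' codes are indexed under every expansion member, so ambiguous
#' typings match exactly when the patient's two-field allele is a
#' member. Exact searches intersect the zero-mismatch sets across
#' loci; single-mismatch searches relax one locus at a time. Index
#' creation is idempotent.
#'
#' @param registry Registry tibble (see [generate_registry()]).
#' @param codes Code table; defaults to the one attached to the
#'   registry.
#' @return An object of class `"hla_match_index"`.
#' @export
build_match_index <- function(registry, codes = hla_codes(registry)) {
  n <- nrow(registry)
  idx <- list(n = n, donor_id = registry$donor_id, codes = codes,
              typed = list(), g0 = list(), g1 = list())
  for (locus in hla_loci) {
    e1 <- registry[[paste0(locus, "_1")]]
    e2 <- registry[[paste0(locus, "_2")]]
    idx$typed[[locus]] <- !is.na(e1) & !is.na(e2)
    for (res in c("low", "medium")) {
      k1 <- donor_entry_keys(e1, res, codes)
      k2 <- donor_entry_keys(e2, res, codes)
      l1 <- lengths(k1); l2 <- lengths(k2)

      # allele index
      simple <- l1 == 1L & l2 == 1L
      hard <- which(!simple)
      idx_s <- which(simple)
      u1 <- unlist(k1[idx_s]); u2 <- unlist(k2[idx_s])
      het <- u1 != u2
      hard_keys <- lapply(hard, function(i) unique(c(k1[[i]], k2[[i]])))
      donor_vec <- c(idx_s, idx_s[het], rep.int(hard, lengths(hard_keys)))
      key_vec <- c(u1, u2[het], unlist(hard_keys))
      idx$g1[[paste(locus, res)]] <- hash_index(split(donor_vec, key_vec))

      # genotype index: every sorted key pair the entries can realise
      hard_gkeys <- lapply(hard, function(i) {
        a <- k1[[i]]; b <- k2[[i]]
        if (length(a) == 0 || length(b) == 0) return(character(0))
        grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
        unique(paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b), sep = "/"))
      })
      donor_vec <- c(idx_s, rep.int(hard, lengths(hard_gkeys)))
      key_vec <- c(paste(pmin(u1, u2), pmax(u1, u2), sep = "/"),
                   unlist(hard_gkeys))
      idx$g0[[paste(locus, res)]] <- hash_index(split(donor_vec, key_vec))
    }
  }
  structure(idx, class = "hla_match_index")
}

hash_index <- function(x) {
  list2env(x, envir = new.env(hash = TRUE, parent = emptyenv(),
                              size = max(29L, length(x))))
}

lookup <- function(env, key) {
  if (is.na(key)) return(integer(0))
  v <- env[[key]]
  if (is.null(v)) integer(0) else v
}

# Core set logic shared by find_matches() and batch_match(): row
# indices of matching donors, given the patient's precomputed keys.
matches_for_keys <- function(index, spec, pk) {
  loci <- spec$loci
  res <- spec$resolution
  s0 <- lapply(loci, function(locus) {
    lookup(index$g0[[paste(locus, res)]], pk[[locus]]$geno)
  })
  names(s0) <- loci
  hits <- Reduce(intersect, s0)
  if (spec$max_mismatch == 1) {
    s1 <- lapply(loci, function(locus) {
      tab <- index$g1[[paste(locus, res)]]
      unique(c(lookup(tab, pk[[locus]]$k1), lookup(tab, pk[[locus]]$k2)))
    })
    names(s1) <- loci
    for (lx in loci) {
      relaxed <- Reduce(intersect, c(s1[lx], s0[setdiff(loci, lx)]))
      hits <- unique(c(hits, relaxed))
    }
  }
  typed_all <- Reduce(`&`, index$typed[loci])
  list(hits = sort(hits[typed_all[hits]]),
       excluded_untyped = index$n - sum(typed_all))
}

check_patient_typed <- function(patient, loci) {
  for (locus in loci) {
    if (is.na(patient[[paste0(locus, "_1")]]) ||
        is.na(patient[[paste0(locus, "_2")]])) {
      stop("patient untyped at required locus ", locus, call. = FALSE)
    }
  }
}

#' Find matching donors for one patient
#'
#' Returns the registry donors compatible with the patient's
#' multilocus genotype under a search specification. Donors not typed
#' at every required locus are excluded from the search and counted in
#' `excluded_untyped`. A donor matches when the total allele mismatch
#' count over the required loci (see [locus_mismatch_count()]) does not
#' exceed the allowance. Donor identifiers are returned sorted in
#' registry order, so results are deterministic.
#'
#' @param patient One-row data frame (or list) with two-field typing
#'   columns `A_1`, `A_2`, ..., `DQB1_2` for the required loci, plus
#'   an `id`.
#' @param registry Registry tibble.
#' @param spec A [search_spec()].
#' @param index Optional prebuilt [build_match_index()]; built on the
#'   fly when `NULL`.
#' @return A one-row tibble: `patient_id`, `loci_set`, `resolution`,
#'   `max_mismatch`, `n_matches`, `excluded_untyped` and a list-column
#'   `donor_ids`.
#' @export
find_matches <- function(patient, registry, spec, index = NULL) {
  if (is.null(index)) index <- build_match_index(registry)
  check_patient_typed(patient, spec$loci)
  pk <- lapply(spec$loci, function(locus) {
    patient_keys(patient[[paste0(locus, "_1")]],
                 patient[[paste0(locus, "_2")]], spec$resolution)
  })
  names(pk) <- spec$loci
  m <- matches_for_keys(index, spec, pk)
  tibble::tibble(
    patient_id = patient$id %||% NA_character_,
    loci_set = spec$loci_set,
    resolution = spec$resolution,
    max_mismatch = spec$max_mismatch,
    n_matches = length(m$hits),
    excluded_untyped = m$excluded_untyped,
    donor_ids = list(index$donor_id[m$hits])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Naive-scan reference search
#'
#' Brute-force implementation of the same search contract as
#' [find_matches()]: every eligible donor is compared locus by locus
#' with [locus_mismatch_count()]. Quadratic and slow; kept as the
#' independent oracle the indexed engine is verified against.
#'
#' @inheritParams find_matches
#' @param codes Code table; defaults to the registry's.
#' @return Same one-row tibble as [find_matches()].
#' @export
find_matches_naive <- function(patient, registry, spec,
                               codes = hla_codes(registry)) {
  loci <- spec$loci
  res <- spec$resolution
  check_patient_typed(patient, loci)
  n <- nrow(registry)
  typed <- rep(TRUE, n)
  for (locus in loci) {
    typed <- typed & !is.na(registry[[paste0(locus, "_1")]]) &
      !is.na(registry[[paste0(locus, "_2")]])
  }
  # one patient allele vs a pre-parsed column of donor entries
  # (definitional compatibility, evaluated donor by donor)
  comp_col <- function(p, pd, dcol) {
    pp <- hla_parse(p)
    if (res == "low") {
      out <- pd$field1 == pp$field1
      out[is.na(out)] <- FALSE
      return(out)
    }
    pk <- hla_truncate(p, "medium")
    dk <- ifelse(is.na(pd$field2) | !is.na(pd$code), NA_character_,
                 sprintf("%s*%02d:%02d", pd$locus, pd$field1, pd$field2))
    out <- !is.na(dk) & dk == pk
    code_rows <- which(!is.na(pd$code))
    if (length(code_rows) > 0) {
      hit <- match(hla_format(pd[code_rows, , drop = FALSE]),
                   codes$code_name)
      if (any(is.na(hit))) {
        stop("unknown NMDP code: '", dcol[code_rows][is.na(hit)][1], "'",
             call. = FALSE)
      }
      out[code_rows] <- vapply(codes$expansion[hit],
                               function(e) pk %in% e, logical(1))
    }
    out
  }
  total <- integer(n)
  for (locus in loci) {
    p1 <- patient[[paste0(locus, "_1")]]
    p2 <- patient[[paste0(locus, "_2")]]
    d1 <- registry[[paste0(locus, "_1")]]
    d2 <- registry[[paste0(locus, "_2")]]
    pd1 <- hla_parse(d1); pd2 <- hla_parse(d2)
    c11 <- comp_col(p1, pd1, d1); c12 <- comp_col(p1, pd2, d2)
    c21 <- comp_col(p2, pd1, d1); c22 <- comp_col(p2, pd2, d2)
    # best of the two pairings between the unordered allele pairs
    total <- total + (2L - pmax(c11 + c22, c12 + c21))
  }
  hits <- which(typed & total <= spec$max_mismatch)
  tibble::tibble(
    patient_id = patient$id %||% NA_character_,
    loci_set = spec$loci_set,
    resolution = spec$resolution,
    max_mismatch = spec$max_mismatch,
    n_matches = length(hits),
    excluded_untyped = nrow(registry) - sum(typed),
    donor_ids = list(registry$donor_id[hits])
  )
}

#' Match a whole cohort against a registry
#'
#' Runs the indexed search for every patient and every search
#' specification, reusing one prebuilt index and vectorised patient
#' keys. Per-patient errors (e.g. an untyped required locus) are
#' logged as warnings and yield an `NA` row rather than aborting the
#' batch.
#'
#' @param cohort Cohort tibble (fully typed patients with an `id`
#'   column).
#' @param registry Registry tibble.
#' @param specs List of [search_spec()]s (default: all twelve).
#' @param index Optional prebuilt index.
#' @param keep_donor_ids Keep the `donor_ids` list-column (needed for
#'   donor-composition analyses); dropped by default to save memory.
#' @return A tibble with one row per patient x spec.
#' @export
batch_match <- function(cohort, registry, specs = all_search_specs(),
                        index = NULL, keep_donor_ids = FALSE) {
  if (is.null(index)) index <- build_match_index(registry)
  n <- nrow(cohort)
  # vectorised patient keys, once per locus and resolution
  keyset <- list()
  for (res in unique(vapply(specs, function(s) s$resolution, character(1)))) {
    keyset[[res]] <- lapply(stats::setNames(hla_loci, hla_loci), function(locus) {
      patient_keys(cohort[[paste0(locus, "_1")]],
                   cohort[[paste0(locus, "_2")]], res)
    })
  }
  out <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    s <- specs[[si]]
    ks <- keyset[[s$resolution]]
    nm <- integer(n); exu <- integer(n)
    ids <- if (keep_donor_ids) vector("list", n) else NULL
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      pk <- lapply(ks[s$loci], function(k) {
        list(k1 = k$k1[i], k2 = k$k2[i], geno = k$geno[i])
      })
      if (any(vapply(pk, function(k) is.na(k$geno), logical(1)))) {
        warning("patient ", cohort$id[i], " untyped at a required locus for ",
                s$loci_set, " search", call. = FALSE)
        ok[i] <- FALSE
        next
      }
      m <- matches_for_keys(index, s, pk)
      nm[i] <- length(m$hits)
      exu[i] <- m$excluded_untyped
      if (keep_donor_ids) ids[[i]] <- index$donor_id[m$hits]
    }
    tab <- tibble::tibble(
      patient_id = cohort$id,
      loci_set = s$loci_set,
      resolution = s$resolution,
      max_mismatch = s$max_mismatch,
      n_matches = ifelse(ok, nm, NA_integer_),
      excluded_untyped = ifelse(ok, exu, NA_integer_)
    )
    if (keep_donor_ids) tab$donor_ids <- ids
    out[[si]] <- tab
  }
  dplyr::bind_rows(out)
}

#' Summarise a match table
#'
#' For each search specification: the percentage of patients with at
#' least one match, and the median and maximum number of matches among
#' patients with at least one (the standard registry-search summary
#' table).
#'
#' @param match_tbl Output of [batch_match()].
#' @return A tibble: `loci_set`, `resolution`, `max_mismatch`, `n`,
#'   `pct_at_least_one`, `median_matches`, `max_matches`.
#' @export
summarize_matches <- function(match_tbl) {
  match_tbl %>%
    dplyr::filter(!is.na(.data$n_matches)) %>%
    dplyr::group_by(.data$loci_set, .data$resolution, .data$max_mismatch) %>%
    dplyr::summarise(
      n = dplyr::n(),
      pct_at_least_one = 100 * mean(.data$n_matches >= 1),
      median_matches = ifelse(any(.data$n_matches >= 1),
                              stats::median(.data$n_matches[.data$n_matches >= 1]),
                              NA_real_),
      max_matches = ifelse(any(.data$n_matches >= 1),
                           max(.data$n_matches), NA_real_),
      .groups = "drop"
    )
}
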