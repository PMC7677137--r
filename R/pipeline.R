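# Pipeline orchestration: simulate -> ancestry -> match -> analyze ->
# report, from one config with independent per-stage seed streams.

schema_header <- function(name) sprintf("# hlamatchr %s schema v1", name)

write_artifact <- function(df, path, name) {
  writeLines(schema_header(name), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_artifact <- function(path) {
  if (!file.exists(path)) {
    stop("missing pipeline artifact: ", path, call. = FALSE)
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("artifact ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

typing_cols <- function() paste0(rep(hla_loci, each = 2), "_", 1:2)

#' Read and write pipeline artifacts
#'
#' Cohort and registry tables are stored as CSV with a schema header
#' comment line; the registry's NMDP code table travels as a JSON
#' side-car (`allele_codes.json` next to the registry file).
#'
#' @param path CSV path.
#' @return A cohort or registry tibble.
#' @export
read_cohort <- function(path) {
  df <- read_artifact(path)
  require_columns(df, c("id", "cohort", "self_id", "scd", "q_afr", "q_eur",
                        "q_nat", "mhc_afr_1", "mhc_afr_2", typing_cols()),
                  path)
  df
}

#' @rdname read_cohort
#' @export
read_registry <- function(path) {
  df <- read_artifact(path)
  require_columns(df, c("donor_id", "self_id", "typing_resolution",
                        typing_cols()), path)
  for (cl in typing_cols()) df[[cl]] <- as.character(df[[cl]])
  codes_path <- file.path(dirname(path), "allele_codes.json")
  codes <- if (file.exists(codes_path)) read_hla_codes(codes_path) else
    hla_code_table(list())
  attr(df, "codes") <- codes
  class(df) <- c("hla_registry", class(df))
  df
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

#' Run the full simulation and analysis pipeline
#'
#' Executes the stages `simulate` (haplotype pools, cohort, SNP panel,
#' registry), `ancestry` (supervised estimation of ancestry proportions
#' from the SNP dosages), `match` (all requested registry searches),
#' `analyze` (grouped match rates, odds ratios, matched-size percent
#' decreases, donor composition, rank and proportion tests) and
#' `report` (markdown rendering), writing each stage's artifacts under
#' `out_dir`. Any stage subset can be re-run against artifacts already
#' on disk. The single seed is expanded into independent per-stage
#' streams, so adding a stage never perturbs earlier stages' draws.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; defaults to `config$seed`.
#' @param stages Character subset of
#'   `c("simulate", "ancestry", "match", "analyze", "report")`.
#' @param specs Search specifications for the match stage.
#' @param verbose Emit structured progress lines.
#' @return The run manifest (invisibly): config hash, seed, package
#'   version, per-file checksums.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "hlamatchr_run",
                         seed = config$seed,
                         stages = c("simulate", "ancestry", "match",
                                    "analyze", "report"),
                         specs = all_search_specs(), verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(out_dir, "config.json"),
    pools = file.path(out_dir, "pools.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    registry = file.path(out_dir, "registry.csv"),
    codes = file.path(out_dir, "allele_codes.json"),
    freqs = file.path(out_dir, "parental_freqs.csv"),
    snps = file.path(out_dir, "snps.csv"),
    estimates = file.path(out_dir, "ancestry_estimates.csv"),
    matches = file.path(out_dir, "matches.csv"),
    stats = file.path(out_dir, "stats.json"),
    report = file.path(out_dir, "report.md"),
    manifest = file.path(out_dir, "manifest.json")
  )

  if ("simulate" %in% stages) {
    log_stage(verbose, "simulate", "seed %d: generating pools", config$seed)
    pools <- generate_pools(config)
    selfid <- calibrate_self_id(config)
    log_stage(verbose, "simulate", "self-ID noise %.4f (R^2 %.3f)",
              selfid$sigma, selfid$achieved_r2)
    cohort <- generate_cohort(config, pools, selfid)
    registry <- generate_registry(config, pools)
    freqs <- generate_snp_freqs(config)
    dosages <- generate_snp_dosages(cohort,  freqs,
                                    seed = stage_seed(config$seed, "snp") + 1L)
    write_sim_config(config, paths$config)
    write_artifact(tibble::as_tibble(pools), paths$pools, "pools")
    write_artifact(cohort, paths$cohort, "cohort")
    write_artifact(tibble::as_tibble(registry), paths$registry, "registry")
    write_hla_codes(hla_codes(registry), paths$codes)
    write_artifact(freqs, paths$freqs, "parental_freqs")
    write_artifact(dplyr::bind_cols(tibble::tibble(id = cohort$id),
                                    tibble::as_tibble(dosages)),
                   paths$snps, "snp_dosages")
    log_stage(verbose, "simulate", "cohort %d, registry %d donors",
              nrow(cohort), nrow(registry))
  }

  if ("ancestry" %in% stages) {
    snps <- read_artifact(paths$snps)
    freqs <- read_artifact(paths$freqs)
    require_columns(freqs, c("snp_id", "AFR", "EUR", "NAT"), paths$freqs)
    G <- as.matrix(snps[, -1])
    fit <- estimate_ancestry_all(G, freqs)
    est <- dplyr::bind_cols(tibble::tibble(id = snps$id), fit)
    write_artifact(est, paths$estimates, "ancestry_estimates")
    log_stage(verbose, "ancestry", "%d individuals, %d converged",
              nrow(est), sum(est$converged))
  }

  if ("match" %in% stages) {
    cohort <- read_cohort(paths$cohort)
    registry <- read_registry(paths$registry)
    index <- build_match_index(registry)
    mt <- batch_match(cohort, registry, specs, index, keep_donor_ids = TRUE)
    flat <- mt
    keep <- flat$resolution == "low" & flat$max_mismatch == 0
    flat$donor_ids <- ifelse(
      keep, vapply(flat$donor_ids, paste, character(1), collapse = ";"), "")
    write_artifact(flat, paths$matches, "matches")
    log_stage(verbose, "match", "%d searches, %d with a match", nrow(mt),
              sum(mt$n_matches >= 1, na.rm = TRUE))
  }

  if ("analyze" %in% stages) {
    cohort <- read_cohort(paths$cohort)
    registry <- read_registry(paths$registry)
    est <- read_artifact(paths$estimates)
    mt <- read_artifact(paths$matches)
    mt$donor_ids <- strsplit(
      ifelse(is.na(mt$donor_ids), "", as.character(mt$donor_ids)), ";",
      fixed = TRUE)
    stats_list <- analyze_run(cohort, registry, est, mt, config)
    jsonlite::write_json(stats_list, paths$stats, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    log_stage(verbose, "analyze", "stats written to %s", paths$stats)
  }

  if ("report" %in% stages) {
    stats_list <- jsonlite::read_json(paths$stats, simplifyVector = TRUE)
    writeLines(render_report(stats_list), paths$report)
    log_stage(verbose, "report", "report written to %s", paths$report)
  }

  files <- unlist(paths[setdiff(names(paths), "manifest")])
  files <- files[file.exists(files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("hlamatchr")),
    seed = config$seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# Assemble the statistics report from the run's tables. Contrasts
# follow the registry-equity analysis: "Black" vs "White" self-ID, Q4
# vs Q1 of African ancestry (quartiles of the *estimated* ancestry),
# and 2 vs 0 chromosomes with African MHC; low-resolution full
# matches, with the SCD contrast at 10/10.
analyze_run <- function(cohort, registry, est, mt, config) {
  assign <- cohort %>%
    dplyr::inner_join(est %>% dplyr::select("id", "q_afr_hat"), by = "id") %>%
    dplyr::mutate(
      quartile = as.character(assign_quartiles(.data$q_afr_hat)),
      mhc_dosage = mhc_dosage(.data$mhc_afr_1, .data$mhc_afr_2)
    )
  seed_an <- stage_seed(config$seed, "analyze")
  loci_sets <- c("6/6", "8/8", "10/10")

  m0 <- mt %>% dplyr::filter(.data$resolution == "low",
                             .data$max_mismatch == 0)
  outcome_tbl <- function(ls) {
    m0 %>% dplyr::filter(.data$loci_set == ls) %>%
      dplyr::inner_join(assign, by = c(patient_id = "id"))
  }

  rates <- list(); ors <- list(); decr <- list(); mwu <- list()
  for (ls in loci_sets) {
    ot <- outcome_tbl(ls)
    matched <- ot$n_matches >= 1
    for (grouping in c("self_id", "quartile", "mhc_dosage")) {
      rates[[length(rates) + 1]] <-
        grouped_match_rates(m0 %>% dplyr::filter(.data$loci_set == ls),
                            assign, grouping) %>%
        dplyr::mutate(loci_set = ls, .before = 1)
    }
    contrasts <- list(
      self_id = ot$self_id %in% c("Black", "White") &
        !is.na(ot$self_id),
      quartile = ot$quartile %in% c("Q1", "Q4"),
      mhc_dosage = ot$mhc_dosage %in% c(0, 2)
    )
    exposed <- list(self_id = "Black", quartile = "Q4", mhc_dosage = "2")
    for (g in names(contrasts)) {
      sel <- contrasts[[g]]
      expo <- as.character(ot[[g]][sel]) == exposed[[g]]
      # degenerate contrasts (tiny runs with empty or saturated cells)
      # are reported as NA rather than aborting the analysis
      or <- tryCatch(tidy(odds_ratio(matched[sel], expo)),
                     error = function(e) {
                       tibble::tibble(estimate = NA_real_,
                                      conf.low = NA_real_,
                                      conf.high = NA_real_,
                                      p.value = NA_real_,
                                      logistic_estimate = NA_real_,
                                      corrected = NA)
                     })
      ors[[length(ors) + 1]] <- tibble::tibble(
        loci_set = ls, grouping = g,
        contrast = paste(exposed[[g]], "vs reference"),
        or)
      pd <- tryCatch(
        percent_decrease(matched[sel][!expo], matched[sel][expo],
                         matched_sizes = TRUE, reps = 200,
                         seed = seed_an + length(decr)),
        error = function(e) list(percent = NA_real_, raw = NA_real_,
                                 rate_ref = NA_real_, rate_cmp = NA_real_))
      decr[[length(decr) + 1]] <- tibble::tibble(
        loci_set = ls, grouping = g, percent = pd$percent, raw = pd$raw,
        rate_ref = pd$rate_ref, rate_cmp = pd$rate_cmp)
      counts_ref <- ot$n_matches[sel & !expo_full(ot[[g]], exposed[[g]])]
      counts_ref <- counts_ref[counts_ref >= 1]
      counts_cmp <- ot$n_matches[sel & expo_full(ot[[g]], exposed[[g]])]
      counts_cmp <- counts_cmp[counts_cmp >= 1]
      if (length(counts_ref) >= 2 && length(counts_cmp) >= 2) {
        mwu[[length(mwu) + 1]] <- tibble::tibble(
          loci_set = ls, grouping = g,
          donor_count_test(counts_ref, counts_cmp))
      }
    }
  }

  comp <- mt %>%
    dplyr::filter(.data$loci_set == "6/6", .data$resolution == "low",
                  .data$max_mismatch == 0)
  comp_tabs <- lapply(c("self_id", "quartile", "mhc_dosage"), function(g) {
    donor_composition(comp, registry, assign, g)
  })

  scd_rates <- m0 %>% dplyr::filter(.data$loci_set == "10/10") %>%
    dplyr::inner_join(assign, by = c(patient_id = "id")) %>%
    dplyr::group_by(.data$scd) %>%
    dplyr::summarise(n = dplyr::n(), rate = mean(.data$n_matches >= 1),
                     .groups = "drop")
  scd_on <- scd_rates[scd_rates$scd == TRUE, ]
  scd_off <- scd_rates[scd_rates$scd == FALSE, ]
  scd_test <- if (nrow(scd_on) == 1 && nrow(scd_off) == 1) {
    dplyr::bind_cols(
      two_prop_ztest(scd_on$rate, scd_on$n, scd_off$rate, scd_off$n),
      tibble::tibble(rate_scd = scd_on$rate, n_scd = scd_on$n,
                     rate_non_scd = scd_off$rate, n_non_scd = scd_off$n))
  } else NULL

  main3 <- assign$self_id %in% c("Black", "Mixed", "White")
  list(
    seed = config$seed,
    config_hash = config_hash(config),
    table2 = summarize_matches(mt),
    grouped_rates = dplyr::bind_rows(rates),
    odds_ratios = dplyr::bind_rows(ors),
    percent_decrease = dplyr::bind_rows(decr),
    donor_count_tests = dplyr::bind_rows(mwu),
    donor_composition = dplyr::bind_rows(comp_tabs),
    scd_test = scd_test,
    ancestry_r2 = list(
      estimated = variance_explained(assign$self_id[main3],
                                     assign$q_afr_hat[main3]),
      true = variance_explained(assign$self_id[main3], assign$q_afr[main3])
    ),
    sibling_match_pct = tibble::tibble(
      k = 1:4, percent = round_half_away(100 * sibling_match_prob(1:4), 1))
  )
}

expo_full <- function(v, level) as.character(v) == level

# minimal markdown table formatter (keeps the report dependency-free)
md_table <- function(df, digits = 3) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    return("*(no data)*")
  }
  df <- as.data.frame(df)
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "",
             formatC(x, digits = digits, format = "fg", flag = "#"))
    } else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, rows)
}

#' Render a run's statistics as a markdown report
#'
#' Produces the human-readable analogue of the standard registry
#' tables: the match-summary table (% with at least one match, median
#' and maximum matches), match rates by group, percent decreases, the
#' donor-composition table, and test statistics. Rendering is a pure
#' function of the stats list, so regenerating the report from the
#' same JSON is byte-identical.
#'
#' @param stats_list Statistics list as written to `stats.json` by
#'   [run_pipeline()] (or read back with `jsonlite::read_json`).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(stats_list) {
  s <- stats_list
  t2 <- as.data.frame(s$table2)
  if (nrow(t2) > 0) {
    t2 <- t2[, c("loci_set", "resolution", "max_mismatch",
                 "pct_at_least_one", "median_matches", "max_matches")]
    names(t2) <- c("Loci", "Resolution", "Mismatches allowed",
                   "% at least one match", "Median number of matches",
                   "Maximum number of matches")
  }
  c(
    "# Registry match analysis",
    "",
    sprintf("Seed %s, config `%s`.", s$seed, s$config_hash),
    "",
    "## Match summary",
    "",
    md_table(t2),
    "",
    "## Match rates by group (low resolution, full match)",
    "",
    md_table(s$grouped_rates),
    "",
    "## Odds ratios (most vs least African)",
    "",
    md_table(s$odds_ratios),
    "",
    "## Percent decrease in chance of a match (matched group sizes)",
    "",
    md_table(s$percent_decrease),
    "",
    "## Donor self-identification composition (6/6, low resolution)",
    "",
    md_table(s$donor_composition),
    "",
    "## Donor-count comparisons (Mann-Whitney U)",
    "",
    md_table(s$donor_count_tests),
    "",
    "## SCD vs non-SCD match rate (10/10, low resolution)",
    "",
    md_table(s$scd_test),
    "",
    "## Variance in African ancestry explained by self-identification",
    "",
    md_table(as.data.frame(s$ancestry_r2)),
    "",
    "## Probability of an HLA-identical sibling",
    "",
    md_table(as.data.frame(s$sibling_match_pct))
  )
}
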