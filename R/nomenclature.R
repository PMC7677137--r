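#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

#' Classical HLA loci covered by the package
#'
#' The five classical transplantation loci used in 6/6 (A, B, DRB1),
#' 8/8 (+C) and 10/10 (+DQB1) unrelated-donor searches.
#'
#' @format Character vector of length 5.
#' @export
hla_loci <- c("A", "B", "C", "DRB1", "DQB1")

# Loci required by each search stringency.
loci_for_set <- function(loci_set) {
  switch(loci_set,
    "6/6"   = c("A", "B", "DRB1"),
    "8/8"   = c("A", "B", "C", "DRB1"),
    "10/10" = c("A", "B", "C", "DRB1", "DQB1"),
    stop("unknown loci set: ", loci_set, call. = FALSE)
  )
}

#' Parse HLA allele names
#'
#' Parses WHO-nomenclature allele names (`"A*34:02"`, `"B*07"`,
#' `"A*34:02:01G"`) and NMDP-style multiple-allele codes
#' (`"A*34:ABXY"`, an alphabetic second field) into a structured tibble.
#' Only the five classical loci `A`, `B`, `C`, `DRB1`, `DQB1` are
#' accepted.
#'
#' @param x Character vector of allele names. `NA` entries are passed
#'   through as all-`NA` rows (untyped slots).
#' @return A tibble with one row per input and columns
#'   `allele` (the input), `locus`, `field1` (integer allele group),
#'   `field2` (integer protein field, `NA` for one-field names and
#'   codes), `field3` (integer, synonymous-level field if present),
#'   `g_group` (logical, `TRUE` for names with a `G` suffix),
#'   `code` (character NMDP code label, `NA` for plain alleles) and
#'   `kind` (`"allele"` or `"code"`).
#' @examples
#' hla_parse(c("A*34:02", "A*34:02:01G", "B*07", "DRB1*13:ABC"))
#' @export
hla_parse <- function(x) {
  x <- as.character(x)
  out <- tibble::tibble(
    allele = x,
    locus = NA_character_,
    field1 = NA_integer_,
    field2 = NA_integer_,
    field3 = NA_integer_,
    g_group = NA,
    code = NA_character_,
    kind = NA_character_
  )
  live <- !is.na(x)
  if (!any(live)) return(out)

  rx <- "^(A|B|C|DRB1|DQB1)\\*([0-9]+)(?::([0-9]+|[A-Z]{2,}))?(?::([0-9]+))?(G)?$"
  m <- stringr::str_match(x[live], rx)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    tok <- x[live][bad][1]
    # distinguish unknown locus from a malformed string for the message
    loc <- stringr::str_match(tok, "^([A-Za-z0-9]+)\\*")[, 2]
    if (!is.na(loc) && !(loc %in% hla_loci)) {
      stop("unknown HLA locus in allele name: '", tok, "'", call. = FALSE)
    }
    stop("malformed HLA allele name: '", tok, "'", call. = FALSE)
  }

  f2raw <- m[, 4]
  is_code <- !is.na(f2raw) & stringr::str_detect(f2raw, "^[A-Z]")
  g <- !is.na(m[, 6])
  if (any(is_code & g)) {
    stop("NMDP code with G suffix is not a valid name: '",
         x[live][is_code & g][1], "'", call. = FALSE)
  }
  out$locus[live] <- m[, 2]
  out$field1[live] <- as.integer(m[, 3])
  out$field2[live] <- ifelse(is_code, NA_integer_,
                             suppressWarnings(as.integer(f2raw)))
  out$field3[live] <- as.integer(m[, 5])
  out$g_group[live] <- g
  out$code[live] <- ifelse(is_code, f2raw, NA_character_)
  out$kind[live] <- ifelse(is_code, "code", "allele")
  out
}

#' Format parsed alleles back to canonical names
#'
#' Canonical form zero-pads numeric fields to two digits
#' (`"A*34:02"`), so `hla_format(hla_parse(s))` reproduces the
#' canonical spelling of `s`.
#'
#' @param parsed A tibble from [hla_parse()].
#' @return Character vector of canonical allele names.
#' @export
hla_format <- function(parsed) {
  pad <- function(f) sprintf("%02d", f)
  s <- paste0(parsed$locus, "*", pad(parsed$field1))
  has2 <- !is.na(parsed$field2)
  s[has2] <- paste0(s[has2], ":", pad(parsed$field2[has2]))
  isc <- !is.na(parsed$code)
  s[isc] <- paste0(parsed$locus[isc], "*", pad(parsed$field1[isc]), ":",
                   parsed$code[isc])
  has3 <- !is.na(parsed$field3)
  s[has3] <- paste0(s[has3], ":", pad(parsed$field3[has3]))
  s[which(parsed$g_group)] <- paste0(s[which(parsed$g_group)], "G")
  s[is.na(parsed$locus)] <- NA_character_
  s
}

#' Truncate alleles to a search resolution
#'
#' Low resolution keeps the allele-group field only (`A*34:02` becomes
#' `A*34`); medium resolution keeps the first two fields, dropping any
#' further fields and the G-group suffix (`A*34:02:01G` becomes
#' `A*34:02`). Truncation is idempotent.
#'
#' Medium-resolution truncation of a one-field name cannot be
#' performed: the protein-level field is unknown, so the result is `NA`
#' (the "insufficient resolution" signal used by the match engine's
#' conservative rule for one-field donor typings).
#'
#' @param x Character vector of allele names (plain alleles; NMDP codes
#'   are truncated to their one-field prefix at low resolution and
#'   passed through unchanged at medium resolution, where expansion
#'   handles them).
#' @param resolution `"low"` or `"medium"`.
#' @return Character vector of truncated canonical names.
#' @examples
#' hla_truncate("A*34:02", "low")          # "A*34"
#' hla_truncate("A*34:02:01G", "medium")   # "A*34:02"
#' @export
hla_truncate <- function(x, resolution = c("low", "medium")) {
  resolution <- match.arg(resolution)
  p <- hla_parse(x)
  if (resolution == "low") {
    out <- ifelse(is.na(p$locus), NA_character_,
                  paste0(p$locus, "*", sprintf("%02d", p$field1)))
    return(out)
  }
  # medium: codes pass through untouched; one-field plain names -> NA
  out <- rep(NA_character_, nrow(p))
  isc <- !is.na(p$code)
  out[isc] <- hla_format(p[isc, , drop = FALSE])
  two <- !isc & !is.na(p$field2)
  out[two] <- paste0(p$locus[two], "*", sprintf("%02d", p$field1[two]),
                     ":", sprintf("%02d", p$field2[two]))
  out
}

#' NMDP-style multiple-allele code tables
#'
#' A code table maps a code name such as `"A*34:ABXY"` to the set of
#' two-field alleles the ambiguous typing may denote. Every member of
#' the expansion shares the code's locus and allele-group field.
#'
#' `hla_code_table()` builds a validated table from a named list;
#' `read_hla_codes()`/`write_hla_codes()` read and write the JSON
#' interchange format (an object mapping code name to an array of
#' allele names).
#'
#' @param expansions Named list: names are code names, values character
#'   vectors of two-field allele names.
#' @return A tibble with columns `code_name`, `locus`, `field1`,
#'   `code`, and a list-column `expansion`.
#' @examples
#' hla_code_table(list("A*34:AB" = c("A*34:01", "A*34:02")))
#' @export
hla_code_table <- function(expansions) {
  if (length(expansions) == 0) {
    return(tibble::tibble(code_name = character(), locus = character(),
                          field1 = integer(), code = character(),
                          expansion = list()))
  }
  stopifnot(!is.null(names(expansions)), all(nzchar(names(expansions))))
  p <- hla_parse(names(expansions))
  if (any(p$kind != "code")) {
    stop("not an NMDP code name: '", p$allele[p$kind != "code"][1], "'",
         call. = FALSE)
  }
  tab <- tibble::tibble(
    code_name = hla_format(p),
    locus = p$locus,
    field1 = p$field1,
    code = p$code,
    expansion = purrr::map(unname(expansions), function(e) {
      pe <- hla_parse(e)
      if (nrow(pe) == 0) stop("empty code expansion", call. = FALSE)
      if (any(is.na(pe$field2))) {
        stop("code expansions must be two-field alleles", call. = FALSE)
      }
      hla_format(pe)
    })
  )
  for (i in seq_len(nrow(tab))) {
    pe <- hla_parse(tab$expansion[[i]])
    if (any(pe$locus != tab$locus[i]) || any(pe$field1 != tab$field1[i])) {
      stop("expansion members of ", tab$code_name[i],
           " must share its locus and allele group", call. = FALSE)
    }
  }
  tab
}

#' @rdname hla_code_table
#' @param path Path to a JSON code table.
#' @export
read_hla_codes <- function(path) {
  hla_code_table(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname hla_code_table
#' @param codes A code table tibble.
#' @export
write_hla_codes <- function(codes, path) {
  x <- stats::setNames(codes$expansion, codes$code_name)
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# Expand an allele entry (plain or code) to the two-field names a
# patient allele could be checked against. Returns character vector
# (possibly empty when the entry cannot be resolved at medium res).
expand_entry_medium <- function(allele, codes) {
  p <- hla_parse(allele)
  if (!is.na(p$code[1])) {
    hit <- which(codes$code_name == hla_format(p))
    if (length(hit) == 0) {
      stop("unknown NMDP code: '", allele, "'", call. = FALSE)
    }
    return(codes$expansion[[hit[1]]])
  }
  if (is.na(p$field2[1])) return(character(0)) # insufficient resolution
  hla_truncate(allele, "medium")
}

#' Allele-level compatibility between a patient and a donor typing
#'
#' At low resolution a patient allele is compatible with any donor
#' entry sharing its allele-group field (`A*34:02` matches any variant
#' of `A*34`). At medium resolution both fields must agree after
#' truncation; a donor NMDP code is compatible when the patient's
#' two-field name is a member of the code's expansion. A one-field
#' donor typing is never compatible at medium resolution (it cannot be
#' confirmed without re-typing).
#'
#' @param patient Character vector of patient allele names (two-field).
#' @param donor Character vector of donor entries (alleles or codes),
#'   recycled against `patient`.
#' @param resolution `"low"` or `"medium"`.
#' @param codes Code table from [hla_code_table()] (only needed when
#'   donor entries contain codes).
#' @return Logical vector.
#' @examples
#' hla_compatible("A*34:02", "A*34:01", "low")     # TRUE
#' hla_compatible("A*34:02", "A*34:01", "medium")  # FALSE
#' @export
hla_compatible <- function(patient, donor, resolution = c("low", "medium"),
                           codes = hla_code_table(list())) {
  resolution <- match.arg(resolution)
  n <- max(length(patient), length(donor))
  patient <- rep_len(patient, n)
  donor <- rep_len(donor, n)
  pp <- hla_parse(patient)
  pd <- hla_parse(donor)
  if (any(pp$locus != pd$locus, na.rm = TRUE)) {
    stop("cross-locus allele comparison", call. = FALSE)
  }
  if (resolution == "low") {
    return(pp$field1 == pd$field1)
  }
  out <- logical(n)
  pkey <- hla_truncate(patient, "medium")
  for (i in seq_len(n)) {
    dk <- expand_entry_medium(donor[i], codes)
    out[i] <- !is.na(pkey[i]) && pkey[i] %in% dk
  }
  out
}

#' Allele mismatch count at one locus
#'
#' Counts mismatched alleles between a patient and a donor genotype at
#' a single locus: `2 - m`, where `m` is the largest number of
#' compatible patient/donor allele pairs over the two possible pairings
#' of the unordered genotypes. Registry searches that allow "a mismatch
#' at a single allele" (5/6, 7/8, 9/10) sum this count over loci.
#'
#' @param patient Length-2 character vector (homozygotes repeated).
#' @param donor Length-2 character vector of donor entries.
#' @inheritParams hla_compatible
#' @return Integer in `0:2`.
#' @export
locus_mismatch_count <- function(patient, donor,
                                 resolution = c("low", "medium"),
                                 codes = hla_code_table(list())) {
  resolution <- match.arg(resolution)
  stopifnot(length(patient) == 2, length(donor) == 2)
  if (any(is.na(patient)) || any(is.na(donor))) {
    stop("untyped locus: mismatch count undefined", call. = FALSE)
  }
  cmp <- function(p, d) hla_compatible(p, d, resolution, codes)
  # the two bijections between unordered pairs
  m1 <- sum(cmp(patient[1], donor[1]), cmp(patient[2], donor[2]))
  m2 <- sum(cmp(patient[1], donor[2]), cmp(patient[2], donor[1]))
  as.integer(2L - max(m1, m2))
}
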