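ROMAN_NUMERALS <- c(
  "i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x",
  "xi", "xii", "xiii", "xiv", "xv", "xvi", "xvii", "xviii", "xix", "xx"
)

# accent-strip, lowercase, non [a-z0-9] -> space. Shared by normalize_name()
# and type inference so both see the same token stream.
prep_tokens <- function(x) {
  x <- strip_accents(x)
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  stringr::str_squish(x)
}

# tokens ordered longest-first so multi-word phrases win over acronyms
ordered_type_tokens <- function(lexicon) {
  tok <- lexicon$type_tokens
  tok[order(-nchar(names(tok)), seq_along(tok))]
}

#' Build a match-ready facility name
#'
#' Turns a raw facility name into the normalized string used for fuzzy
#' matching, applying in order: (1) accent transliteration and removal of any
#' character outside `[a-z0-9 ]`; (2) lowercasing; (3) removal of
#' facility-type tokens ("PS", "Case de Sante", ...) at token boundaries;
#' (4) acronym expansion ("St." -> "saint"); (5) conversion of a terminal
#' roman-numeral token to digits ("iii" -> "3"); (6) stripping of leading and
#' trailing French filler words and whitespace collapse.
#'
#' The function is total and idempotent. It can return an empty string (a
#' name consisting only of type tokens); callers flag, but keep, such
#' records.
#'
#' @param raw Character vector of raw facility names.
#' @param lexicon A [normalization_lexicon()].
#' @return Character vector of normalized names.
#' @examples
#' lex <- normalization_lexicon()
#' normalize_name(c("Facility iii", "St. Jean", "Case de Santé Ndiaye"), lex)
#' @export
normalize_name <- function(raw, lexicon = normalization_lexicon()) {
  x <- prep_tokens(raw)

  for (token in names(ordered_type_tokens(lexicon))) {
    x <- stringr::str_replace_all(
      x, paste0("\\b", token, "\\b"), " "
    )
  }

  for (acro in names(lexicon$acronym_map)) {
    x <- stringr::str_replace_all(
      x, paste0("\\b", acro, "\\b"), lexicon$acronym_map[[acro]]
    )
  }

  x <- stringr::str_squish(x)

  # terminal roman numeral -> arabic
  roman <- ROMAN_NUMERALS[seq_len(lexicon$roman_numeral_limit)]
  last <- stringr::str_extract(x, "[a-z]+$")
  hit <- !is.na(last) & last %in% roman
  if (any(hit)) {
    x[hit] <- paste0(
      stringr::str_remove(x[hit], "[a-z]+$"),
      match(last[hit], ROMAN_NUMERALS)
    )
  }

  if (length(lexicon$filler_tokens)) {
    filler <- paste(lexicon$filler_tokens, collapse = "|")
    x <- stringr::str_remove(x, paste0("^(?:(?:", filler, ")\\s+)+"))
    x <- stringr::str_remove(x, paste0("(?:\\s+(?:", filler, "))+$"))
  }

  stringr::str_squish(x)
}

#' Standardize a source-reported facility type
#'
#' Maps free-text type labels ("Poste de Santé", "PS", "Hôpital", already
#' standardized codes, ...) to the package's type codes. Unrecognized or
#' missing labels become `"unknown"`.
#'
#' @param x Character vector of raw type labels.
#' @param lexicon A [normalization_lexicon()].
#' @return Character vector of [facility_types()] codes.
#' @export
standardize_type <- function(x, lexicon = normalization_lexicon()) {
  out <- rep("unknown", length(x))
  prepared <- prep_tokens(ifelse(is.na(x), "", x))

  # already-canonical codes pass through
  as_code <- gsub(" ", "_", prepared)
  is_code <- as_code %in% facility_types()
  out[is_code] <- as_code[is_code]

  tok <- ordered_type_tokens(lexicon)
  todo <- !is_code & prepared != ""
  for (i in seq_along(tok)) {
    hit <- todo & stringr::str_detect(
      prepared, paste0("\\b", names(tok)[i], "\\b")
    )
    out[hit] <- tok[[i]]
    todo <- todo & !hit
  }

  # bare pyramid words ("poste", "centre", "case", "health post" -> no)
  bare <- c(
    poste = "poste_de_sante", centre = "centre_de_sante",
    case = "case_de_sante", autre = "autre", prive = "autre",
    dispensaire = "autre", doctors = "autre"
  )
  for (w in names(bare)) {
    hit <- todo & stringr::str_detect(prepared, paste0("\\b", w, "\\b"))
    out[hit] <- bare[[w]]
    todo <- todo & !hit
  }
  out
}

#' Infer facility type from the name string
#'
#' Facility lists often omit an explicit type column but encode it in the
#' name ("PS Nemataba", "Nemataba Poste de Santé"). Scans the name for type
#' tokens (longest first) and returns the corresponding type code, or
#' `"unknown"` when no token is present. Total function: never errors.
#'
#' @param fac_name Character vector of raw facility names.
#' @param lexicon A [normalization_lexicon()].
#' @return Character vector of [facility_types()] codes.
#' @examples
#' infer_type_from_name(c("PS Nemataba", "Hôpital de Fatick", "Nemataba"))
#' @export
infer_type_from_name <- function(fac_name, lexicon = normalization_lexicon()) {
  prepared <- prep_tokens(fac_name)
  out <- rep("unknown", length(fac_name))
  tok <- ordered_type_tokens(lexicon)
  todo <- prepared != ""
  for (i in seq_along(tok)) {
    hit <- todo & stringr::str_detect(
      prepared, paste0("\\b", names(tok)[i], "\\b")
    )
    out[hit] <- tok[[i]]
    todo <- todo & !hit
  }
  out
}

#' Normalize a table of source records
#'
#' Adds the match-ready columns to raw source records: `region_std`
#' (canonical region, verbatim + flagged when unmatched), `fac_type_std`
#' (standardized source type, falling back to name-based inference), and
#' `match_name` (via [normalize_name()]). Records whose name normalizes to
#' the empty string are flagged (`name_flagged`), never dropped.
#'
#' @param records Tibble of source records (from [load_source()]).
#' @param lexicon A [normalization_lexicon()].
#' @param regions Canonical region list for blocking.
#' @return The input tibble with columns `region_std`, `region_matched`,
#'   `fac_type_std`, `match_name`, `name_flagged` added.
#' @export
normalize_records <- function(records,
                              lexicon = normalization_lexicon(),
                              regions = senegal_regions()) {
  stopifnot(all(c("fac_name_orig", "region_orig") %in% names(records)))
  type_src <- standardize_type(records$fac_type_orig, lexicon)
  type_name <- infer_type_from_name(records$fac_name_orig, lexicon)
  records |>
    dplyr::mutate(
      region_std = canonical_region(.data$region_orig, regions),
      region_matched = .data$region_std %in% regions,
      fac_type_std = ifelse(type_src == "unknown", type_name, type_src),
      match_name = normalize_name(.data$fac_name_orig, lexicon),
      name_flagged = !nzchar(.data$match_name)
    )
}
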