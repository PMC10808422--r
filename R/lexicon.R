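#' Senegal's 14 first-level administrative regions
#'
#' Canonical region labels used for blocking. Matching against this list is
#' case-, accent- and separator-insensitive (`canonical_region()`), so
#' "SAINT LOUIS", "Saint-Louis" and "saint louis" all canonicalize to
#' "Saint-Louis".
#'
#' @return Character vector of the 14 region names.
#' @export
senegal_regions <- function() {
  c(
    "Dakar", "Diourbel", "Fatick", "Kaffrine", "Kaolack", "Kedougou",
    "Kolda", "Louga", "Matam", "Saint-Louis", "Sedhiou", "Tambacounda",
    "Thies", "Ziguinchor"
  )
}

#' Facility-type levels
#'
#' The Senegalese health pyramid as used throughout the package, ordered from
#' community level upward: health hut (case de sante), health post (poste de
#' sante), health center (centre de sante), hospital (hopital). `autre`
#' (other: private clinics, "doctors", unspecified) and `unknown` never count
#' toward headline facility totals.
#'
#' @param ladder_only If `TRUE`, return only the four pyramid levels in
#'   upgrade order (hut < post < center < hospital).
#' @return Character vector of type codes.
#' @export
facility_types <- function(ladder_only = FALSE) {
  ladder <- c("case_de_sante", "poste_de_sante", "centre_de_sante", "hopital")
  if (ladder_only) ladder else c(ladder, "autre", "unknown")
}

# rank on the upgrade ladder; autre/unknown get NA
type_ladder_rank <- function(type) {
  match(type, facility_types(ladder_only = TRUE))
}

#' Name-normalization lexicon
#'
#' Bundles the vocabularies used by [normalize_name()]: facility-type tokens
#' to strip from names, acronym expansions, and the cap on roman-numeral
#' conversion. Type tokens are matched accent-insensitively at token
#' boundaries, longest token first, so "poste de sante" is removed before
#' "ps" and "ps" never eats letters inside a word.
#'
#' @param type_tokens Named character vector: token (already lowercase,
#'   accent-free) -> facility-type code. Order does not matter; tokens are
#'   applied longest-first.
#' @param acronym_map Named character vector: acronym token -> expansion.
#' @param filler_tokens Leading/trailing French filler words stripped after
#'   type-token removal, so "hopital de fatick" and "cs fatick" share the
#'   match name "fatick".
#' @param roman_numeral_limit Largest roman numeral converted (terminal token
#'   only).
#' @return A list with class `"normalization_lexicon"`.
#' @examples
#' lex <- normalization_lexicon()
#' normalize_name("Case de Santé Ndiaye", lex)
#' @export
normalization_lexicon <- function(
    type_tokens = default_type_tokens(),
    acronym_map = c(st = "saint", ste = "sainte", ndr = "notre dame"),
    filler_tokens = c("de", "du", "des", "d", "la", "le", "l"),
    roman_numeral_limit = 20) {
  stopifnot(
    is.character(type_tokens), !is.null(names(type_tokens)),
    !anyDuplicated(names(acronym_map)),
    roman_numeral_limit >= 1, roman_numeral_limit <= 20
  )
  structure(
    list(
      type_tokens = type_tokens,
      acronym_map = acronym_map,
      filler_tokens = filler_tokens,
      roman_numeral_limit = as.integer(roman_numeral_limit)
    ),
    class = "normalization_lexicon"
  )
}

#' Default facility-type token vocabulary
#'
#' Token -> type-code map used both to infer a facility's type from its name
#' (`infer_type_from_name()`) and to strip type strings before matching.
#' Editable: pass a modified copy to [normalization_lexicon()].
#'
#' @return Named character vector (names are tokens, values are type codes).
#' @export
default_type_tokens <- function() {
  c(
    "poste de sante"  = "poste_de_sante",
    "postes de sante" = "poste_de_sante",
    "centre de sante" = "centre_de_sante",
    "case de sante"   = "case_de_sante",
    "cases de sante"  = "case_de_sante",
    "hopital"         = "hopital",
    "centre hospitalier regional"     = "hopital",
    "centre hospitalier universitaire" = "hopital",
    "clinique"        = "autre",
    "cabinet"         = "autre",
    "ps"              = "poste_de_sante",
    "cs"              = "centre_de_sante",
    "cds"             = "case_de_sante",
    "eps"             = "hopital",
    "chr"             = "hopital",
    "chu"             = "hopital"
  )
}

strip_accents <- function(x) {
  stringi::stri_trans_general(x, "Latin-ASCII")
}

#' Canonicalize region names
#'
#' Matches free-text region labels against a canonical list (default:
#' Senegal's 14 regions) ignoring case, accents and space/hyphen differences.
#' Unmatched values are kept verbatim so downstream blocking still works, and
#' are reported via the `region_matched` attribute-free companion
#' [normalize_records()] flag.
#'
#' @param region Character vector of raw region labels.
#' @param regions Canonical region list.
#' @return Character vector: canonical name where matched, the original
#'   (trimmed) string otherwise; `NA` stays `NA`.
#' @export
canonical_region <- function(region, regions = senegal_regions()) {
  key <- function(x) {
    x <- strip_accents(tolower(trimws(x)))
    gsub("[^a-z0-9]+", "", x)
  }
  idx <- match(key(region), key(regions))
  out <- ifelse(is.na(idx), trimws(region), regions[idx])
  out[is.na(region)] <- NA_character_
  out
}
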