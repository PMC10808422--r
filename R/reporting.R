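HEADLINE_EXCLUDED <- c("autre", "unknown")

# half-up rounding to match printed-percentage conventions
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_headline_type <- function(type) {
  !(gsub(" ", "_", type) %in% HEADLINE_EXCLUDED)
}

#' Facility counts and GPS coverage by region and type
#'
#' Tabulates the consolidated list by region and facility type (plus
#' `"all"`-type and `"National"` rollups): number of facilities, number with
#' at least one assigned coordinate set, and percent coverage to one
#' decimal. Facilities typed "autre" or "unknown" do not contribute — they
#' are carried in the list but excluded from headline totals.
#'
#' @param cfl Consolidated facility list from [build_cfl()].
#' @return Tibble with `region`, `fac_type`, `n_facilities`, `n_with_gps`,
#'   `pct_with_gps`. Region/type combinations with no facilities are
#'   omitted.
#' @export
coverage_summary <- function(cfl) {
  base <- cfl |>
    dplyr::filter(is_headline_type(.data$group_fac_type)) |>
    dplyr::mutate(has_gps = !is.na(.data$group_latitude) &
                    !is.na(.data$group_longitude))
  if (nrow(base) == 0) {
    return(tibble::tibble(
      region = character(), fac_type = character(),
      n_facilities = integer(), n_with_gps = integer(),
      pct_with_gps = numeric()
    ))
  }
  cells <- function(df, region_label) {
    by_type <- df |>
      dplyr::summarise(
        n_facilities = dplyr::n(),
        n_with_gps = sum(.data$has_gps),
        .by = "group_fac_type"
      ) |>
      dplyr::rename(fac_type = "group_fac_type")
    all_row <- tibble::tibble(
      fac_type = "all",
      n_facilities = nrow(df),
      n_with_gps = sum(df$has_gps)
    )
    dplyr::bind_rows(all_row, by_type) |>
      dplyr::mutate(region = region_label, .before = 1)
  }
  out <- dplyr::bind_rows(
    cells(base, "National"),
    base |>
      dplyr::group_split(.data$region) |>
      purrr::map(~ cells(.x, .x$region[[1]])) |>
      purrr::list_rbind()
  )
  out |>
    dplyr::mutate(
      pct_with_gps = round_half_up(100 * .data$n_with_gps /
                                     .data$n_facilities, 1)
    ) |>
    dplyr::arrange(.data$region != "National", .data$region,
                   .data$fac_type != "all", .data$fac_type)
}

#' Multi-type facility summary
#'
#' Counts match groups whose member records originally carried two or more
#' distinct (known) facility types across sources — typically upgraded
#' facilities, occasionally misclassification — and how many of those had
#' their final type resolved by source recency.
#'
#' @param full_list Member-level records with `match_id` and
#'   `fac_type_std`.
#' @param cfl Consolidated facility list (for the denominator and final
#'   types).
#' @return List with `n_multitype`, `pct_of_cfl` (one decimal),
#'   `n_resolved`, and `per_type` (tibble of multitype counts by final
#'   group type).
#' @export
multitype_summary <- function(full_list, cfl) {
  stopifnot(all(c("match_id", "fac_type_std") %in% names(full_list)))
  per_group <- full_list |>
    dplyr::summarise(
      n_types = dplyr::n_distinct(
        .data$fac_type_std[.data$fac_type_std != "unknown"]
      ),
      .by = "match_id"
    )
  multi_ids <- per_group$match_id[per_group$n_types >= 2]
  cfl_multi <- cfl[cfl$match_id %in% multi_ids, , drop = FALSE]
  n_multi <- length(multi_ids)
  list(
    n_multitype = n_multi,
    pct_of_cfl = round_half_up(100 * n_multi / max(nrow(cfl), 1L), 1),
    n_resolved = sum(grepl("most recent source reports",
                           cfl_multi$data_notes, fixed = TRUE)),
    per_type = cfl_multi |>
      dplyr::count(.data$group_fac_type, name = "n_multitype") |>
      dplyr::arrange(.data$group_fac_type)
  )
}

#' Compare consolidated counts against published reference lists
#'
#' Computes national facility counts from the consolidated list (overall and
#' per pyramid type, headline types only) and differences them against a
#' reference table of previously published counts.
#'
#' @param cfl Consolidated facility list.
#' @param reference Tibble with columns `list_name`, `all`, `hopital`,
#'   `centre_de_sante`, `poste_de_sante`, `case_de_sante` (counts may be
#'   `NA`); see [reference_counts()].
#' @return Tibble: one row per reference list with its counts and
#'   `diff_*` columns (consolidated minus reference).
#' @export
compare_counts <- function(cfl, reference = reference_counts()) {
  needed <- c("list_name", "all", "hopital", "centre_de_sante",
              "poste_de_sante", "case_de_sante")
  missing_cols <- setdiff(needed, names(reference))
  if (length(missing_cols)) {
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  headline <- cfl[is_headline_type(cfl$group_fac_type), , drop = FALSE]
  code <- gsub(" ", "_", headline$group_fac_type)
  cfl_counts <- c(
    all = nrow(headline),
    hopital = sum(code == "hopital"),
    centre_de_sante = sum(code == "centre_de_sante"),
    poste_de_sante = sum(code == "poste_de_sante"),
    case_de_sante = sum(code == "case_de_sante")
  )
  out <- reference[, needed]
  for (col in names(cfl_counts)) {
    out[[paste0("diff_", col)]] <- unname(cfl_counts[[col]]) - out[[col]]
  }
  out
}

#' Published national facility counts for Senegal
#'
#' Reference count table transcribed from previously published national
#' facility lists (service-provision-assessment facility frames and the
#' public-only 2021 health map), alongside the consolidated-list totals they
#' were compared to. Shipped as a plain-text transcription for regression
#' display with [compare_counts()]; rows whose per-type cells could not be
#' verified against row totals are not included.
#'
#' @return Tibble with `list_name` and count columns.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "senegal_published_counts.csv",
                      package = "faclink", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
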