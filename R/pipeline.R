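#' Triangulate facility lists into a consolidated facility list
#'
#' End-to-end pipeline: per-source standardization and name normalization,
#' within-source deduplication, pooling, within-region Jaro-Winkler
#' candidate generation, transitive-closure clustering, optional manual
#' review corrections, group-level type/GPS/conflict resolution, and the
#' final consolidated facility list.
#'
#' @param sources Named list of raw source tables (data frames as read from
#'   each file), or character vector of file paths.
#' @param specs Named list of [source_spec()], one per source, aligned with
#'   `sources`.
#' @param source_years Named vector `source_id -> year`; defaults to the
#'   years in `specs`.
#' @param lexicon A [normalization_lexicon()].
#' @param regions Canonical region list.
#' @param match_cfg A [matching_config()].
#' @param hierarchy A [source_hierarchy()] for GPS preference.
#' @param constants A [geo_constants()].
#' @param review Optional review-decision table for
#'   [apply_review_decisions()].
#' @return An object of class `"facility_triangulation"`: a list with
#'   `cfl` (consolidated list), `full_list` (all pooled records with
#'   `match_id`), `groups`, `candidates`, `review_report`, and the
#'   configuration pieces. Has [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' sim <- simulate_registry(synthetic_config(seed = 3, n_facilities = 40,
#'                                           n_sources = 3))
#' fit <- triangulate(sim$sources, sim$specs,
#'                    source_years = sim$source_years)
#' glance(fit)
#' @export
triangulate <- function(sources, specs,
                        source_years = NULL,
                        lexicon = normalization_lexicon(),
                        regions = senegal_regions(),
                        match_cfg = matching_config(),
                        hierarchy = source_hierarchy(),
                        constants = geo_constants(),
                        review = NULL) {
  stopifnot(length(sources) == length(specs))
  if (is.character(sources)) {
    sources <- purrr::map2(sources, specs, load_source)
  } else {
    sources <- purrr::map2(sources, specs, records_from_table)
  }
  if (is.null(source_years)) {
    source_years <- purrr::map_int(specs, function(sp) {
      sp$source_year %||% NA_integer_
    })
    names(source_years) <- purrr::map_chr(specs, "source_id")
  }

  per_source <- purrr::map(sources, function(rec) {
    rec |>
      normalize_records(lexicon, regions) |>
      dedupe_within_source()
  })
  pooled <- pool_sources(per_source)
  # sources missing from the hierarchy rank last, in configuration order
  hierarchy <- complete_hierarchy(
    hierarchy, purrr::map_chr(specs, "source_id")
  )
  candidates <- candidate_pairs(pooled, match_cfg)
  clustered <- cluster_matches(pooled, candidates)
  if (!is.null(review)) {
    clustered <- apply_review_decisions(clustered, review)
  }
  groups <- consolidate_records(
    clustered, source_years = source_years, hierarchy = hierarchy,
    constants = constants, cfg = match_cfg
  )
  cfl <- build_cfl(groups)

  structure(
    list(
      cfl = cfl,
      full_list = clustered,
      groups = groups,
      candidates = candidates,
      review_report = attr(cfl, "review_report"),
      match_cfg = match_cfg,
      hierarchy = hierarchy,
      constants = constants,
      source_years = source_years
    ),
    class = "facility_triangulation"
  )
}

#' @export
print.facility_triangulation <- function(x, ...) {
  g <- glance(x)
  cat("Facility-list triangulation\n")
  cat(sprintf("  pooled records:      %d from %d source(s)\n",
              g$n_records, g$n_sources))
  cat(sprintf("  unique facilities:   %d (%d excluding autre/unknown)\n",
              g$n_groups, g$n_facilities))
  cat(sprintf("  with GPS:            %d (%.1f%%)\n",
              g$n_with_gps, g$pct_with_gps))
  cat(sprintf("  flagged for review:  %d\n", g$n_flagged))
  invisible(x)
}

#' Tidy the consolidated facility list
#'
#' @param x A `facility_triangulation` object.
#' @param ... Unused.
#' @return The consolidated facility list tibble (one row per unique
#'   facility).
#' @method tidy facility_triangulation
#' @export
tidy.facility_triangulation <- function(x, ...) {
  x$cfl
}

#' One-row summary of a triangulation
#'
#' @param x A `facility_triangulation` object.
#' @param ... Unused.
#' @return One-row tibble: record/source/group counts, headline facility
#'   count (excluding autre/unknown), GPS coverage, flags, and GPS
#'   discordance among multi-GPS groups.
#' @method glance facility_triangulation
#' @export
glance.facility_triangulation <- function(x, ...) {
  cfl <- x$cfl
  headline <- cfl[is_headline_type(cfl$group_fac_type), , drop = FALSE]
  disc <- discordance_stats(x$full_list, x$constants)
  tibble::tibble(
    n_records = nrow(x$full_list),
    n_sources = dplyr::n_distinct(x$full_list$source_id),
    n_groups = nrow(cfl),
    n_facilities = nrow(headline),
    n_with_gps = sum(!is.na(headline$group_latitude)),
    pct_with_gps = round_half_up(
      100 * sum(!is.na(headline$group_latitude)) /
        max(nrow(headline), 1L), 1
    ),
    n_flagged = sum(cfl$data_flagged),
    n_multi_gps = disc$n_multi_gps,
    frac_discordant = disc$frac_exceeding
  )
}

#' Write the consolidated and full facility lists
#'
#' Writes the two UTF-8 CSV outputs: the consolidated list (one row per
#' unique facility, Table-style schema, 5-decimal WGS84 coordinates) and the
#' full list (every pooled source record with its original attributes,
#' per-source coordinates and `match_id`).
#'
#' @param x A `facility_triangulation` object.
#' @param cfl_path,full_path Output file paths.
#' @return `x`, invisibly.
#' @export
write_cfl <- function(x, cfl_path, full_path = NULL) {
  readr::write_csv(x$cfl, cfl_path, na = "")
  if (!is.null(full_path)) {
    full <- x$full_list |>
      dplyr::mutate(
        latitude = round(.data$latitude, 5),
        longitude = round(.data$longitude, 5)
      ) |>
      dplyr::select(
        "match_id", "record_id", "source_id", "fac_name_orig",
        "fac_type_orig", "fac_type_std", "ownership_orig", "region_orig",
        "region_std", "department_orig", "district_orig", "latitude",
        "longitude", "match_name"
      )
    readr::write_csv(full, full_path, na = "")
  }
  invisible(x)
}
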