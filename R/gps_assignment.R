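#' GPS source-preference hierarchy
#'
#' Ordered tiers of source ids used to pick one authoritative coordinate set
#' per facility group. The default encodes the preference used for the
#' Senegal consolidated list — emergency-operations data (COUS) first, then
#' non-2017 service-provision-assessment frames (2016, 2015, 2014), then the
#' SPA 2017 frame, then ESRI, HDX, and the Maina et al. Africa-wide dataset
#' — i.e. government-associated sources before external compilations.
#' Sources absent from the hierarchy rank after all listed ones, in the
#' order they are first seen in the data.
#'
#' @param tiers List of character vectors; earlier tiers are preferred, and
#'   order within a tier breaks ties.
#' @return A list with class `"source_hierarchy"`.
#' @export
source_hierarchy <- function(tiers = list(
    "cous",
    c("spa2016", "spa2015", "spa2014"),
    "spa2017",
    "esri",
    "hdx",
    "maina")) {
  flat <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop("a source_id may appear in at most one tier: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  }
  structure(list(tiers = tiers, order = flat), class = "source_hierarchy")
}

# preference rank per source: hierarchy position; unlisted sources rank
# after every listed one, ordered by source id so ranking is independent of
# record order
hierarchy_rank <- function(source_id, hierarchy) {
  listed <- match(source_id, hierarchy$order)
  extra <- sort(unique(source_id[is.na(listed)]), method = "radix")
  rank_extra <- match(source_id, extra) + length(hierarchy$order)
  ifelse(is.na(listed), rank_extra, listed)
}

# append sources missing from the hierarchy as trailing tiers, in the given
# (configuration) order
complete_hierarchy <- function(hierarchy, source_ids) {
  missing <- setdiff(source_ids, hierarchy$order)
  if (length(missing)) {
    hierarchy <- source_hierarchy(c(hierarchy$tiers, as.list(missing)))
  }
  hierarchy
}

round5 <- function(x) round(x, 5)

#' Assign one coordinate set per facility group
#'
#' If only one member of a group carries coordinates, those are used. When
#' several sources report coordinates, the highest-ranked source in the
#' preference hierarchy wins; within a source, the lowest `row_index` wins
#' and the group is flagged (an unresolved within-source duplicate).
#' Coordinates are rounded to 5 decimal places. Groups without any
#' coordinates get missing values.
#'
#' @param records Clustered records with `match_id`, `source_id`,
#'   `row_index`, `latitude`, `longitude`.
#' @param hierarchy A [source_hierarchy()].
#' @return Tibble with `match_id`, `group_latitude`, `group_longitude`,
#'   `group_gps_source`, `gps_note`.
#' @export
assign_gps <- function(records, hierarchy = source_hierarchy()) {
  stopifnot(all(c("match_id", "source_id", "row_index", "latitude",
                  "longitude") %in% names(records)))
  # ranks must be computed over the whole pool so unlisted-source order is
  # globally consistent
  records$.rank <- hierarchy_rank(records$source_id, hierarchy)

  with_gps <- records |>
    dplyr::filter(!is.na(.data$latitude), !is.na(.data$longitude))

  if (nrow(with_gps) == 0) {
    chosen <- tibble::tibble(
      match_id = character(), group_latitude = numeric(),
      group_longitude = numeric(), group_gps_source = character(),
      gps_note = character()
    )
  } else {
    chosen <- with_gps |>
      dplyr::mutate(
        n_from_source = dplyr::n(),
        .by = c("match_id", "source_id")
      ) |>
      dplyr::arrange(.data$.rank, .data$row_index) |>
      dplyr::summarise(
        group_latitude = round5(.data$latitude[[1]]),
        group_longitude = round5(.data$longitude[[1]]),
        group_gps_source = .data$source_id[[1]],
        gps_note = if (.data$n_from_source[[1]] > 1) {
          paste0("multiple GPS rows from source ", .data$source_id[[1]],
                 "; kept first by row order")
        } else {
          ""
        },
        .by = "match_id"
      )
  }

  dplyr::distinct(records, .data$match_id) |>
    dplyr::left_join(chosen, by = "match_id") |>
    dplyr::mutate(gps_note = dplyr::coalesce(.data$gps_note, "")) |>
    dplyr::arrange(.data$match_id)
}

#' Count distinct coordinate sets per group
#'
#' Number of unique (latitude, longitude) pairs among a group's members
#' after rounding to 5 decimal places — coordinates that agree to 5 decimals
#' count as a single set.
#'
#' @param records Clustered records with `match_id` and coordinates.
#' @return Tibble with `match_id`, `n_gps`.
#' @export
count_distinct_gps <- function(records) {
  stopifnot(all(c("match_id", "latitude", "longitude") %in% names(records)))
  records |>
    dplyr::mutate(
      .lat5 = round5(.data$latitude),
      .lon5 = round5(.data$longitude)
    ) |>
    dplyr::summarise(
      n_gps = dplyr::n_distinct(
        paste(.data$.lat5, .data$.lon5)[!is.na(.data$.lat5) &
                                          !is.na(.data$.lon5)]
      ),
      .by = "match_id"
    ) |>
    dplyr::arrange(.data$match_id)
}
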