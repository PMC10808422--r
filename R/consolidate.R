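join_notes <- function(...) {
  parts <- c(...)
  parts <- unique(parts[!is.na(parts) & nzchar(parts)])
  paste(parts, collapse = "; ")
}

# modal value, ties broken by C-locale sort
modal <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  cands <- sort(names(tab)[tab == tab[[1]]], method = "radix")
  cands[[1]]
}

#' Resolve conflicting facility types within groups
#'
#' A match group whose members report a single (known) type keeps it. When
#' members disagree and all reported types sit on the upgrade ladder
#' (hut < post < center < hospital) and at least one contributing source is
#' dated, the type reported by the most recent dated source wins — the usual
#' situation being a facility upgraded between source years (e.g. a health
#' hut that became a health post); the resolution is noted as an upgrade or
#' downgrade. Conflicts without date information, or involving off-ladder
#' types, resolve to the majority type (ties to the higher level) with a
#' conflict note.
#'
#' @param records Clustered records with `match_id` and `fac_type_std`.
#' @param source_years Named integer vector mapping `source_id` to year
#'   (`NA` = undated, treated as oldest).
#' @return Tibble with `match_id`, `group_fac_type`, `type_note`.
#' @export
resolve_fac_type <- function(records, source_years = NULL) {
  stopifnot(all(c("match_id", "source_id", "fac_type_std") %in%
                  names(records)))
  if (is.null(source_years)) source_years <- setNames(integer(), character())
  yr <- unname(source_years[records$source_id])
  records$.year <- ifelse(is.na(yr), -Inf, as.numeric(yr))

  resolve_one <- function(types, years) {
    known <- types != "unknown"
    ktypes <- types[known]
    kyears <- years[known]
    distinct <- unique(ktypes)
    if (length(distinct) == 0) {
      return(list(type = "unknown", note = ""))
    }
    if (length(distinct) == 1) {
      return(list(type = distinct, note = ""))
    }
    ranks <- type_ladder_rank(distinct)
    on_ladder <- !anyNA(ranks)
    dated <- any(is.finite(kyears))
    if (on_ladder && dated) {
      latest <- kyears == max(kyears)
      cand <- ktypes[latest]
      tab <- sort(table(cand), decreasing = TRUE)
      top <- names(tab)[tab == tab[[1]]]
      chosen <- top[which.max(type_ladder_rank(top))]
      others <- setdiff(distinct, chosen)
      direction <- if (all(type_ladder_rank(others) <
                           type_ladder_rank(chosen))) {
        "upgrade"
      } else if (all(type_ladder_rank(others) > type_ladder_rank(chosen))) {
        "downgrade"
      } else {
        "mixed change"
      }
      note <- sprintf(
        "facility type %s across sources (%s); most recent source reports %s",
        direction, paste(sort(distinct, method = "radix"), collapse = ", "),
        chosen
      )
      return(list(type = chosen, note = note))
    }
    # undated or off-ladder conflict: majority, tie -> higher level
    tab <- sort(table(ktypes), decreasing = TRUE)
    top <- names(tab)[tab == tab[[1]]]
    if (length(top) == 1) {
      chosen <- top
    } else {
      r <- type_ladder_rank(top)
      chosen <- if (all(is.na(r))) {
        sort(top, method = "radix")[[1]]
      } else {
        top[which.max(ifelse(is.na(r), -Inf, r))]
      }
    }
    note <- sprintf(
      "conflicting facility types (%s) resolved to %s by %s",
      paste(sort(distinct, method = "radix"), collapse = ", "), chosen,
      if (length(top) == 1) "majority" else "tie-break to higher level"
    )
    list(type = chosen, note = note)
  }

  records |>
    dplyr::summarise(
      res = list(resolve_one(.data$fac_type_std, .data$.year)),
      .by = "match_id"
    ) |>
    dplyr::mutate(
      group_fac_type = purrr::map_chr(.data$res, "type"),
      type_note = purrr::map_chr(.data$res, "note")
    ) |>
    dplyr::select("match_id", "group_fac_type", "type_note") |>
    dplyr::arrange(.data$match_id)
}

# one row per group with membership-derived fields
group_summary <- function(records) {
  records |>
    dplyr::summarise(
      region = modal(.data$region_std),
      match_name = modal(.data$match_name),
      n_source = dplyr::n_distinct(.data$source_id),
      source_list = paste(sort(unique(.data$source_id), method = "radix"),
                          collapse = ", "),
      departments = list(sort(unique(
        .data$department_orig[!is.na(.data$department_orig)]
      ), method = "radix")),
      districts = list(sort(unique(
        .data$district_orig[!is.na(.data$district_orig)]
      ), method = "radix")),
      member_note = join_notes(
        if (any(.data$name_flagged)) "member name normalizes to empty" else "",
        if (!all(.data$region_matched)) "unrecognized region label" else "",
        if ("review_notes" %in% names(records)) {
          unlist(strsplit(.data$review_notes, "; ", fixed = TRUE))
        } else {
          ""
        }
      ),
      .by = "match_id"
    )
}

#' Flag groups with conflicting coordinates
#'
#' Adds a `geo_note` to every group whose members' coordinates spread more
#' than the review distance (1 km by default): matches implying a distance
#' above that are candidates for mismatched facilities and need review.
#'
#' @param groups Group-level tibble (must have `match_id`).
#' @param records Clustered member records with coordinates.
#' @param constants A [geo_constants()].
#' @return `groups` with a `geo_note` column (re-computed, never appended).
#' @export
flag_geo_conflicts <- function(groups, records,
                               constants = geo_constants()) {
  spread <- max_pairwise_distance(records, constants)
  groups |>
    dplyr::select(-dplyr::any_of("geo_note")) |>
    dplyr::left_join(
      spread |>
        dplyr::mutate(
          geo_note = ifelse(
            !is.na(.data$max_pairwise_km) &
              .data$max_pairwise_km > constants$review_distance_km,
            sprintf("GPS spread %.2f km exceeds %.1f km across sources",
                    .data$max_pairwise_km, constants$review_distance_km),
            ""
          )
        ) |>
        dplyr::select("match_id", "geo_note"),
      by = "match_id"
    )
}

#' Flag same-name ambiguity patterns
#'
#' Applies the three recurring ambiguity patterns seen when triangulating
#' facility lists:
#' (a) distinct groups sharing a match name and region but differing in type
#' are cross-noted as possibly one upgraded facility — unless their assigned
#' coordinates lie further apart than the review distance, in which case
#' they are noted as name-sharing but geographically distinct;
#' (b) groups sharing name, type and region but sitting in different
#' departments or health districts stay separate and are noted;
#' (c) group-name pairs just above the matching threshold (distance in
#' `(threshold, threshold + margin]`) are collected into a review report,
#' attached as the `"review_report"` attribute.
#'
#' @param groups Group-level tibble with `match_id`, `region`, `match_name`,
#'   `group_fac_type`, `group_latitude`, `group_longitude`, `departments`,
#'   `districts`.
#' @param constants A [geo_constants()].
#' @param cfg A [matching_config()] (for the threshold).
#' @param margin Width of the near-threshold review band.
#' @return `groups` with a `name_note` column and a `"review_report"`
#'   attribute.
#' @export
flag_same_name_conflicts <- function(groups, constants = geo_constants(),
                                     cfg = matching_config(),
                                     margin = 0.1) {
  groups <- dplyr::select(groups, -dplyr::any_of("name_note"))
  notes <- setNames(rep("", nrow(groups)), groups$match_id)

  disjoint <- function(a, b) length(a) && length(b) && !length(intersect(a, b))

  by_name <- split(seq_len(nrow(groups)),
                   paste(groups$region, groups$match_name, sep = "\r"))
  for (idx in by_name[lengths(by_name) >= 2]) {
    for (pair in asplit(combn(idx, 2), 2)) {
      i <- pair[[1]]; j <- pair[[2]]
      gi <- groups[i, ]; gj <- groups[j, ]
      if (gi$group_fac_type != gj$group_fac_type) {
        d <- if (!is.na(gi$group_latitude) && !is.na(gj$group_latitude)) {
          haversine_km(gi$group_latitude, gi$group_longitude,
                       gj$group_latitude, gj$group_longitude, constants)
        } else {
          NA_real_
        }
        if (!is.na(d) && d > constants$review_distance_km) {
          msg_i <- sprintf(
            "shares name with %s (different type) but GPS %.2f km apart; treated as distinct",
            gj$match_id, d)
          msg_j <- sprintf(
            "shares name with %s (different type) but GPS %.2f km apart; treated as distinct",
            gi$match_id, d)
        } else {
          msg_i <- sprintf("possibly the same facility as %s (same name, different type; candidate upgrade)",
                           gj$match_id)
          msg_j <- sprintf("possibly the same facility as %s (same name, different type; candidate upgrade)",
                           gi$match_id)
        }
        notes[i] <- join_notes(notes[i], msg_i)
        notes[j] <- join_notes(notes[j], msg_j)
      } else if (disjoint(gi$departments[[1]], gj$departments[[1]]) ||
                 disjoint(gi$districts[[1]], gj$districts[[1]])) {
        msg <- function(other) sprintf(
          "same name and type as %s in a different department/district; kept separate",
          other$match_id)
        notes[i] <- join_notes(notes[i], msg(gj))
        notes[j] <- join_notes(notes[j], msg(gi))
      }
    }
  }

  # (c) near-threshold pairs, by region, on group representative names
  report <- list()
  by_region <- split(seq_len(nrow(groups)), groups$region)
  for (idx in by_region[lengths(by_region) >= 2]) {
    cmb <- combn(idx, 2)
    d <- jaro_winkler_distance(groups$match_name[cmb[1, ]],
                               groups$match_name[cmb[2, ]], cfg)
    near <- which(d > cfg$threshold & d <= cfg$threshold + margin)
    if (length(near)) {
      report[[length(report) + 1]] <- tibble::tibble(
        match_id_a = groups$match_id[cmb[1, near]],
        match_id_b = groups$match_id[cmb[2, near]],
        match_name_a = groups$match_name[cmb[1, near]],
        match_name_b = groups$match_name[cmb[2, near]],
        jw_distance = d[near]
      )
    }
  }
  review_report <- if (length(report)) {
    dplyr::arrange(purrr::list_rbind(report), .data$match_id_a,
                   .data$match_id_b)
  } else {
    tibble::tibble(
      match_id_a = character(), match_id_b = character(),
      match_name_a = character(), match_name_b = character(),
      jw_distance = numeric()
    )
  }

  groups$name_note <- unname(notes)
  attr(groups, "review_report") <- review_report
  groups
}

#' Consolidate clustered records into match groups
#'
#' Runs the full group-level resolution: membership summary, facility-type
#' resolution ([resolve_fac_type()]), GPS assignment ([assign_gps()]) and
#' distinct-set counting ([count_distinct_gps()]), geospatial conflict
#' flagging ([flag_geo_conflicts()]) and same-name ambiguity flagging
#' ([flag_same_name_conflicts()]). Deterministic and idempotent: notes are
#' recomputed from scratch, never appended.
#'
#' @param records Clustered, normalized records (with `match_id`).
#' @param source_years Named vector `source_id -> year` for type recency.
#' @param hierarchy A [source_hierarchy()].
#' @param constants A [geo_constants()].
#' @param cfg A [matching_config()].
#' @return Group-level tibble (one row per match group) carrying all
#'   resolved fields and notes, with the near-threshold `"review_report"`
#'   attribute.
#' @export
consolidate_records <- function(records, source_years = NULL,
                                hierarchy = source_hierarchy(),
                                constants = geo_constants(),
                                cfg = matching_config()) {
  if (!"review_notes" %in% names(records)) records$review_notes <- ""
  groups <- group_summary(records) |>
    dplyr::left_join(resolve_fac_type(records, source_years),
                     by = "match_id") |>
    dplyr::left_join(assign_gps(records, hierarchy), by = "match_id") |>
    dplyr::left_join(count_distinct_gps(records), by = "match_id") |>
    flag_geo_conflicts(records, constants) |>
    flag_same_name_conflicts(constants, cfg) |>
    dplyr::arrange(.data$match_id)
  groups
}

# CFL output labels: codes with spaces, per the deposited-list convention
label_fac_type <- function(code) gsub("_", " ", code)

#' Emit the consolidated facility list
#'
#' Formats finalized match groups as the consolidated facility list: one row
#' per unique facility with columns `region`, `match_id`, `match_name`,
#' `group_fac_type` (space-separated labels, e.g. "poste de sante"),
#' `group_latitude`, `group_longitude`, `group_gps_source`, `n_gps`,
#' `n_source`, `source_list`, `data_flagged`, `data_notes`. `data_flagged`
#' is 1 exactly when `data_notes` is non-empty. Rows typed "autre" or
#' "unknown" are carried in the list but excluded from headline counts by
#' the reporting functions.
#'
#' @param groups Output of [consolidate_records()].
#' @return The consolidated facility list as a tibble.
#' @export
build_cfl <- function(groups) {
  cfl <- groups |>
    dplyr::mutate(
      data_notes = purrr::pmap_chr(
        list(.data$type_note, .data$gps_note, .data$geo_note,
             .data$name_note, .data$member_note),
        join_notes
      ),
      data_flagged = as.integer(nzchar(.data$data_notes)),
      group_fac_type = label_fac_type(.data$group_fac_type)
    ) |>
    dplyr::select(
      "region", "match_id", "match_name", "group_fac_type",
      "group_latitude", "group_longitude", "group_gps_source",
      "n_gps", "n_source", "source_list", "data_flagged", "data_notes"
    ) |>
    dplyr::arrange(.data$match_id)
  attr(cfl, "review_report") <- attr(groups, "review_report")
  cfl
}
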