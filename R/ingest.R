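CANONICAL_ATTRS <- c(
  "name", "type", "ownership", "region", "department", "district",
  "latitude", "longitude"
)

#' Describe one facility-list source
#'
#' A source spec names a list (short unique `source_id`), dates it
#' (`source_year`, `NA` when unknown), and maps the file's column headers to
#' the canonical attributes `name`, `type`, `ownership`, `region`,
#' `department`, `district`, `latitude`, `longitude`. At minimum `name` and
#' `region` must be mapped.
#'
#' @param source_id Short unique label, e.g. `"cous"`, `"spa2016"`.
#' @param column_map Named character vector: canonical attribute ->
#'   column header in the file.
#' @param source_year Integer year the list reflects, or `NA`.
#' @param has_gps Whether the source carries coordinates.
#' @return A list with class `"source_spec"`.
#' @examples
#' source_spec("cous", c(name = "nom", region = "region"), 2019)
#' @export
source_spec <- function(source_id, column_map, source_year = NA_integer_,
                        has_gps = all(c("latitude", "longitude") %in%
                                        names(column_map))) {
  stopifnot(
    is.character(source_id), length(source_id) == 1L, nzchar(source_id),
    is.character(column_map), !is.null(names(column_map))
  )
  unknown <- setdiff(names(column_map), CANONICAL_ATTRS)
  if (length(unknown)) {
    stop("column_map names must be canonical attributes; unknown: ",
         paste(unknown, collapse = ", "))
  }
  missing_req <- setdiff(c("name", "region"), names(column_map))
  if (length(missing_req)) {
    stop("column_map must map at least name and region; missing: ",
         paste(missing_req, collapse = ", "))
  }
  structure(
    list(
      source_id = source_id,
      source_year = as.integer(source_year),
      column_map = column_map,
      has_gps = isTRUE(has_gps)
    ),
    class = "source_spec"
  )
}

parse_coordinate <- function(x, bound, what, source_id) {
  if (is.numeric(x)) {
    num <- as.numeric(x)
  } else {
    num <- suppressWarnings(as.numeric(gsub(",", ".", trimws(as.character(x)))))
    bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(num)
    if (any(bad)) {
      warning(sprintf("%s: %d malformed %s value(s) set to missing",
                      source_id, sum(bad), what), call. = FALSE)
    }
  }
  out_of_range <- !is.na(num) & abs(num) > bound
  if (any(out_of_range)) {
    warning(sprintf("%s: %d out-of-range %s value(s) set to missing",
                    source_id, sum(out_of_range), what), call. = FALSE)
    num[out_of_range] <- NA_real_
  }
  num
}

records_from_table <- function(raw, spec) {
  cm <- spec$column_map
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols)) {
    stop(spec$source_id, ": mapped column(s) not present in file: ",
         paste(missing_cols, collapse = ", "))
  }
  grab <- function(attr) {
    if (attr %in% names(cm)) raw[[cm[[attr]]]] else rep(NA, nrow(raw))
  }
  out <- tibble::tibble(
    source_id = spec$source_id,
    row_index = seq_len(nrow(raw)),
    fac_name_orig = as.character(grab("name")),
    fac_type_orig = as.character(grab("type")),
    ownership_orig = as.character(grab("ownership")),
    region_orig = as.character(grab("region")),
    department_orig = as.character(grab("department")),
    district_orig = as.character(grab("district")),
    latitude = parse_coordinate(grab("latitude"), 90, "latitude",
                                spec$source_id),
    longitude = parse_coordinate(grab("longitude"), 180, "longitude",
                                 spec$source_id)
  )
  empty <- is.na(out$fac_name_orig) | !nzchar(trimws(out$fac_name_orig))
  if (any(empty)) {
    message(sprintf("%s: rejected %d row(s) with empty facility name",
                    spec$source_id, sum(empty)))
  }
  out <- out[!empty, ]
  message(sprintf("%s: loaded %d record(s)", spec$source_id, nrow(out)))
  out
}

#' Read one facility list
#'
#' Reads a delimited UTF-8 text file with a header row, applies the spec's
#' column map, parses coordinates to decimal degrees (malformed or
#' out-of-range values become missing, with a warning), and drops rows with
#' an empty facility name (with a message). Every retained row becomes one
#' source record keyed by `(source_id, row_index)`.
#'
#' @param path Path to the delimited file.
#' @param spec A [source_spec()].
#' @param delim Field delimiter (default comma).
#' @return Tibble of source records.
#' @export
load_source <- function(path, spec, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  records_from_table(raw, spec)
}

#' Remove duplicate rows within one source
#'
#' Collapses exact duplicates on the key (normalized name, canonical region,
#' standardized type) to a single record. Among duplicates, a record with
#' coordinates is preferred; ties break by lowest `row_index`, so the result
#' is order-invariant and idempotent.
#'
#' @param records Normalized records (see [normalize_records()]) from a
#'   single source.
#' @return Deduplicated tibble; the number of removed rows is reported via a
#'   message and the `"n_removed"` attribute.
#' @export
dedupe_within_source <- function(records) {
  if (nrow(records) == 0) return(records)
  if (length(unique(records$source_id)) > 1L) {
    stop("dedupe_within_source() expects records from a single source")
  }
  stopifnot(all(c("match_name", "region_std", "fac_type_std") %in%
                  names(records)))
  out <- records |>
    dplyr::arrange(
      .data$match_name, .data$region_std, .data$fac_type_std,
      is.na(.data$latitude) | is.na(.data$longitude), .data$row_index
    ) |>
    dplyr::distinct(
      .data$match_name, .data$region_std, .data$fac_type_std,
      .keep_all = TRUE
    ) |>
    dplyr::arrange(.data$row_index)
  n_removed <- nrow(records) - nrow(out)
  if (n_removed > 0) {
    message(sprintf("%s: removed %d within-source duplicate(s)",
                    records$source_id[[1]], n_removed))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Pool deduplicated sources into one database
#'
#' Concatenates per-source record tables into the pooled observation
#' database, adding the globally unique `record_id` = `source_id:row_index`.
#'
#' @param per_source List of record tibbles, one per source, each already
#'   deduplicated within source.
#' @return Pooled tibble with a `record_id` column.
#' @export
pool_sources <- function(per_source) {
  if (length(per_source) == 0) {
    return(tibble::tibble(
      source_id = character(), row_index = integer(), record_id = character()
    ))
  }
  ids <- purrr::map_chr(per_source, function(x) {
    if (nrow(x) == 0) NA_character_ else unique(x$source_id)
  })
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids)) {
    stop("colliding source_ids across pooled lists: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pooled <- dplyr::bind_rows(per_source) |>
    dplyr::mutate(record_id = paste(.data$source_id, .data$row_index,
                                    sep = ":"))
  message(sprintf("pooled %d record(s) from %d source(s)",
                  nrow(pooled), length(ids)))
  pooled
}

#' Read a run-configuration file
#'
#' Parses a YAML run configuration with a `sources` block (one entry per
#' source: `column_map`, `year`, optional `tier`), an optional `hierarchy`
#' block (ordered tiers of source ids for GPS preference) and optional
#' `matching` overrides (`threshold`, `prefix_weight`, `prefix_max`).
#'
#' @param path Path to the YAML file.
#' @return List with elements `specs` (named list of [source_spec()]),
#'   `hierarchy` ([source_hierarchy()]), and `matching`
#'   ([matching_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sources)) stop("run configuration must have a sources block")
  specs <- purrr::imap(cfg$sources, function(s, id) {
    source_spec(
      source_id = id,
      column_map = unlist(s$column_map),
      source_year = s$year %||% NA_integer_
    )
  })
  hier <- if (!is.null(cfg$hierarchy)) {
    source_hierarchy(lapply(cfg$hierarchy, unlist))
  } else {
    source_hierarchy()
  }
  m <- cfg$matching %||% list()
  list(
    specs = specs,
    hierarchy = hier,
    matching = matching_config(
      threshold = m$threshold %||% 0.2,
      prefix_weight = m$prefix_weight %||% 0.1,
      prefix_max = m$prefix_max %||% 4L
    )
  )
}
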