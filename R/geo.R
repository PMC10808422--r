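#' Geospatial constants
#'
#' Mean Earth radius and the two distance rules used during verification:
#' match groups whose coordinates spread more than `review_distance_km`
#' (default 1 km) are flagged for review, and multi-GPS groups spreading
#' more than `discordance_distance_km` (default 2 km) count as discordant in
#' validation summaries. Both rules are strictly greater-than.
#'
#' @param earth_radius_km Sphere radius in km (default 6371, mean Earth
#'   radius).
#' @param review_distance_km Review-flag threshold in km.
#' @param discordance_distance_km Discordance threshold in km.
#' @return A list with class `"geo_constants"`.
#' @export
geo_constants <- function(earth_radius_km = 6371,
                          review_distance_km = 1,
                          discordance_distance_km = 2) {
  stopifnot(earth_radius_km > 0, review_distance_km > 0,
            discordance_distance_km > 0)
  structure(
    list(
      earth_radius_km = earth_radius_km,
      review_distance_km = review_distance_km,
      discordance_distance_km = discordance_distance_km
    ),
    class = "geo_constants"
  )
}

#' Great-circle (Haversine) distance
#'
#' Distance in kilometres between WGS84 decimal-degree points on a sphere:
#' `2 R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2)))`.
#' Vectorized; recycles arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @param constants A [geo_constants()] supplying the sphere radius.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0) # ~111.19 km per degree of arc
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2,
                         constants = geo_constants()) {
  check_range <- function(x, bound, what) {
    if (any(abs(x) > bound, na.rm = TRUE)) {
      stop("out-of-range ", what, ": |", what, "| must be <= ", bound)
    }
  }
  check_range(lat1, 90, "latitude"); check_range(lat2, 90, "latitude")
  check_range(lon1, 180, "longitude"); check_range(lon2, 180, "longitude")
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * constants$earth_radius_km * asin(pmin(1, sqrt(a)))
}

#' Maximum pairwise distance within groups
#'
#' For each match group, the maximum Haversine distance over all pairs of
#' member records carrying coordinates; `NA` for groups with fewer than two
#' geolocated members.
#'
#' @param records Clustered records with `match_id`, `latitude`,
#'   `longitude`.
#' @param constants A [geo_constants()].
#' @return Tibble with columns `match_id`, `n_geolocated`,
#'   `max_pairwise_km`.
#' @export
max_pairwise_distance <- function(records, constants = geo_constants()) {
  stopifnot(all(c("match_id", "latitude", "longitude") %in% names(records)))
  records |>
    dplyr::filter(!is.na(.data$latitude), !is.na(.data$longitude)) |>
    dplyr::summarise(
      n_geolocated = dplyr::n(),
      max_pairwise_km = if (dplyr::n() < 2) NA_real_ else {
        cmb <- combn(dplyr::n(), 2)
        max(haversine_km(
          .data$latitude[cmb[1, ]], .data$longitude[cmb[1, ]],
          .data$latitude[cmb[2, ]], .data$longitude[cmb[2, ]],
          constants
        ))
      },
      .by = "match_id"
    ) |>
    dplyr::right_join(
      dplyr::distinct(records, .data$match_id),
      by = "match_id"
    ) |>
    dplyr::mutate(n_geolocated = dplyr::coalesce(.data$n_geolocated, 0L)) |>
    dplyr::arrange(.data$match_id)
}

#' GPS discordance summary
#'
#' Counts match groups with at least two *distinct* coordinate sets (after
#' 5-decimal rounding) and, among those, the share whose maximum pairwise
#' distance exceeds the discordance threshold (2 km by default) — a marker
#' for verification needs.
#'
#' @param records Clustered records with coordinates.
#' @param constants A [geo_constants()].
#' @return One-row tibble: `n_multi_gps`, `n_exceeding`, `frac_exceeding`
#'   (`NA` when there is no multi-GPS group).
#' @export
discordance_stats <- function(records, constants = geo_constants()) {
  distinct_sets <- count_distinct_gps(records)
  spread <- max_pairwise_distance(records, constants)
  per_group <- dplyr::inner_join(distinct_sets, spread, by = "match_id")
  multi <- per_group[per_group$n_gps >= 2, , drop = FALSE]
  n_multi <- nrow(multi)
  n_exceeding <- sum(multi$max_pairwise_km > constants$discordance_distance_km,
                     na.rm = TRUE)
  tibble::tibble(
    n_multi_gps = n_multi,
    n_exceeding = n_exceeding,
    frac_exceeding = if (n_multi == 0) NA_real_ else n_exceeding / n_multi
  )
}
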