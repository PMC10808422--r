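# small hand-built fixtures shared across tests

# a raw source table in the canonical test header layout
raw_source <- function(...) {
  rows <- list(...)
  tibble::tibble(
    nom = purrr::map_chr(rows, 1),
    type = purrr::map_chr(rows, 2),
    region = purrr::map_chr(rows, 3),
    latitude = purrr::map_dbl(rows, 4),
    longitude = purrr::map_dbl(rows, 5)
  )
}

test_spec <- function(source_id, year = NA_integer_) {
  source_spec(
    source_id,
    column_map = c(name = "nom", type = "type", region = "region",
                   latitude = "latitude", longitude = "longitude"),
    source_year = year
  )
}

# normalized single-source records straight from field values
make_records <- function(source_id, names, region = "Fatick",
                         types = NA_character_, lat = NA_real_,
                         lon = NA_real_, department = NA_character_,
                         district = NA_character_, year = NA_integer_) {
  n <- length(names)
  tibble::tibble(
    source_id = source_id,
    row_index = seq_len(n),
    fac_name_orig = names,
    fac_type_orig = rep_len(types, n),
    ownership_orig = NA_character_,
    region_orig = rep_len(region, n),
    department_orig = rep_len(department, n),
    district_orig = rep_len(district, n),
    latitude = rep_len(lat, n),
    longitude = rep_len(lon, n)
  ) |>
    normalize_records()
}

# pooled + clustered records for group-level tests
make_clustered <- function(...) {
  recs <- list(...)
  pooled <- suppressMessages(pool_sources(recs))
  cand <- candidate_pairs(pooled)
  cluster_matches(pooled, cand)
}

small_sim <- function(seed = 42, n_facilities = 120, n_sources = 3, ...) {
  simulate_registry(synthetic_config(
    seed = seed, n_facilities = n_facilities, n_sources = n_sources, ...
  ))
}

quiet_triangulate <- function(...) {
  suppressMessages(suppressWarnings(triangulate(...)))
}
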