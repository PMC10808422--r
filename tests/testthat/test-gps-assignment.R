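test_that("the GPS hierarchy prefers sources in the documented order", {
  # COUS beats HDX
  recs <- make_clustered(
    make_records("hdx", "PS Ndiaye", lat = 14.00000, lon = -16.00000),
    make_records("cous", "PS Ndiaye", lat = 14.50000, lon = -16.50000)
  )
  got <- assign_gps(recs)
  expect_equal(got$group_gps_source, "cous")
  expect_equal(got$group_latitude, 14.5)

  # non-2017 SPA beats SPA 2017
  recs2 <- make_clustered(
    make_records("spa2017", "PS Ndiaye", lat = 14.0, lon = -16.0),
    make_records("spa2015", "PS Ndiaye", lat = 14.2, lon = -16.2)
  )
  expect_equal(assign_gps(recs2)$group_gps_source, "spa2015")

  # a single geolocated member is used regardless of rank
  recs3 <- make_clustered(
    make_records("maina", "PS Ndiaye", lat = 14.1, lon = -16.1),
    make_records("cous", "PS Ndiaye")
  )
  got3 <- assign_gps(recs3)
  expect_equal(got3$group_gps_source, "maina")

  # no member GPS -> none
  recs4 <- make_clustered(make_records("cous", "PS Ndiaye"))
  expect_true(is.na(assign_gps(recs4)$group_latitude))
  expect_true(is.na(assign_gps(recs4)$group_gps_source))
})

test_that("unlisted sources rank after the hierarchy", {
  recs <- make_clustered(
    make_records("mystery", "PS Ndiaye", lat = 14.0, lon = -16.0),
    make_records("maina", "PS Ndiaye", lat = 14.2, lon = -16.2)
  )
  expect_equal(assign_gps(recs)$group_gps_source, "maina")
})

test_that("a source contributing two coordinate rows is flagged", {
  a1 <- make_records("a", c("CS Ndiaye", "Ndiaye Alt"),
                     lat = c(14.0, 14.2), lon = c(-16.0, -16.2))
  recs <- suppressMessages(pool_sources(list(a1)))
  recs$match_id <- "X-0001"
  got <- assign_gps(recs)
  expect_equal(got$group_latitude, 14.0)
  expect_match(got$gps_note, "multiple GPS rows")
})

test_that("assignment equals a brute-force rank scan on random groups", {
  hier <- source_hierarchy()
  flat <- hier$order
  set.seed(31)
  n_groups <- 1000
  rows <- purrr::map(seq_len(n_groups), function(g) {
    k <- sample(2:5, 1)
    sids <- sample(c(flat, "extra1", "extra2"), k)
    tibble::tibble(
      match_id = sprintf("G-%04d", g),
      source_id = sids,
      row_index = seq_len(k),
      latitude = ifelse(runif(k) < 0.7, runif(k, 12, 17), NA),
      longitude = ifelse(runif(k) < 0.7, runif(k, -17, -12), NA)
    )
  })
  recs <- purrr::list_rbind(rows)
  recs$latitude[is.na(recs$longitude)] <- NA
  recs$longitude[is.na(recs$latitude)] <- NA
  got <- assign_gps(recs, hier)

  rank_of <- function(sid) {
    r <- match(sid, flat)
    ifelse(is.na(r), length(flat) + match(sid, c("extra1", "extra2")), r)
  }
  for (g in unique(recs$match_id)) {
    members <- recs[recs$match_id == g & !is.na(recs$latitude), ]
    row <- got[got$match_id == g, ]
    if (nrow(members) == 0) {
      expect_true(is.na(row$group_gps_source))
    } else {
      best <- members[order(rank_of(members$source_id),
                            members$row_index), ][1, ]
      expect_equal(row$group_gps_source, best$source_id)
      expect_equal(row$group_latitude, round(best$latitude, 5))
    }
  }

  # permuting member order never changes the assignment
  set.seed(32)
  perm <- recs[sample(nrow(recs)), ]
  got_perm <- assign_gps(perm, hier)
  expect_equal(
    got_perm[order(got_perm$match_id), ],
    got[order(got$match_id), ],
    ignore_attr = TRUE
  )
})

test_that("distinct-GPS counting rounds to 5 decimals first", {
  base <- make_records("a", "PS Ndiaye", lat = 14.123456789,
                       lon = -16.987654321)
  same <- make_records("b", "PS Ndiaye", lat = 14.123459, lon = -16.987649)
  recs <- suppressMessages(pool_sources(list(base, same)))
  recs$match_id <- "X-0001"
  # 14.1234568 vs 14.12346 round to the same 5-decimal pair
  expect_equal(count_distinct_gps(recs)$n_gps, 1)

  differ <- make_records("b", "PS Ndiaye", lat = 14.12348, lon = -16.98765)
  recs2 <- suppressMessages(pool_sources(list(base, differ)))
  recs2$match_id <- "X-0001"
  expect_equal(count_distinct_gps(recs2)$n_gps, 2)

  none <- make_clustered(make_records("a", "PS Ndiaye"))
  expect_equal(count_distinct_gps(none)$n_gps, 0)
})

test_that("n_gps is bounded by geolocated members and zero iff unassigned", {
  sim <- small_sim(seed = 17)
  fit <- quiet_triangulate(sim$sources, sim$specs,
                           source_years = sim$source_years)
  full <- fit$full_list
  n_gps <- count_distinct_gps(full)
  n_geo <- full |>
    dplyr::summarise(
      n = sum(!is.na(latitude) & !is.na(longitude)), .by = match_id
    )
  joined <- dplyr::inner_join(n_gps, n_geo, by = "match_id")
  expect_true(all(joined$n_gps <= joined$n))
  assigned <- assign_gps(full)
  j2 <- dplyr::inner_join(n_gps, assigned, by = "match_id")
  expect_equal(j2$n_gps == 0, is.na(j2$group_latitude))
})
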