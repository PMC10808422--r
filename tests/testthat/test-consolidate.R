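years_demo <- c(old = 2014L, recent = 2021L, mid = 2017L, older = 2015L)

test_that("type conflicts on the ladder resolve to the most recent source", {
  # health hut (2014) later reported as health post (2021): upgrade
  recs <- make_clustered(
    make_records("old", "Nemataba Case de Santé"),
    make_records("recent", "PS Nemataba")
  )
  got <- resolve_fac_type(recs, years_demo)
  expect_equal(got$group_fac_type, "poste_de_sante")
  expect_match(got$type_note, "upgrade")

  # hospital (2015) then health post (2017, 2021): downgrade, still flagged
  recs2 <- make_clustered(
    make_records("older", "Hôpital Ninefecha"),
    make_records("mid", "PS Ninefecha"),
    make_records("recent", "PS Ninefecha")
  )
  got2 <- resolve_fac_type(recs2, years_demo)
  expect_equal(got2$group_fac_type, "poste_de_sante")
  expect_match(got2$type_note, "downgrade")

  # a single reported type needs no note
  recs3 <- make_clustered(
    make_records("old", "PS Seul"),
    make_records("recent", "Seul Poste de Santé")
  )
  got3 <- resolve_fac_type(recs3, years_demo)
  expect_equal(got3$group_fac_type, "poste_de_sante")
  expect_equal(got3$type_note, "")
})

test_that("undated or off-ladder conflicts use majority with tie to higher", {
  # no year information: majority wins
  recs <- make_clustered(
    make_records("s1", "CS Ndar"),
    make_records("s2", "Ndar Centre de Santé"),
    make_records("s3", "Hôpital Ndar")
  )
  got <- resolve_fac_type(recs, NULL)
  expect_equal(got$group_fac_type, "centre_de_sante")
  expect_match(got$type_note, "majority")

  # 1-1 tie: the higher pyramid level wins, with a note
  recs2 <- make_clustered(
    make_records("s1", "CS Tie"),
    make_records("s2", "Hôpital Tie")
  )
  got2 <- resolve_fac_type(recs2, NULL)
  expect_equal(got2$group_fac_type, "hopital")
  expect_match(got2$type_note, "tie")

  # unknown types never override a known one
  recs3 <- make_clustered(
    make_records("s1", "Sans Type"),
    make_records("s2", "PS Sans Type")
  )
  got3 <- resolve_fac_type(recs3, NULL)
  expect_equal(got3$group_fac_type, "poste_de_sante")
  expect_equal(got3$type_note, "")
})

test_that("groups spreading more than 1 km get a geospatial flag", {
  far <- make_clustered(
    make_records("a", "PS Loin", lat = 14.000, lon = -16.0),
    make_records("b", "PS Loin", lat = 14.0135, lon = -16.0)  # ~1.5 km
  )
  near <- make_clustered(
    make_records("a", "PS Pres", lat = 14.000, lon = -16.0),
    make_records("b", "PS Pres", lat = 14.0045, lon = -16.0)  # ~0.5 km
  )
  solo <- make_clustered(make_records("a", "PS Seul", lat = 14, lon = -16))

  g_far <- consolidate_records(far)
  g_near <- consolidate_records(near)
  g_solo <- consolidate_records(solo)
  expect_match(g_far$geo_note, "exceeds 1.0 km")
  expect_equal(g_near$geo_note, "")
  expect_equal(g_solo$geo_note, "")
})

test_that("same-name different-type groups are cross-noted", {
  # CS and Hopital sharing a name in one region, no GPS: candidate upgrade
  recs <- make_clustered(
    make_records("s1", "CS Fatick"),
    make_records("s2", "Hôpital de Fatick")
  )
  # names normalize identically but types differ; they merge by name,
  # so build them as separate groups via distinct regions of one name
  groups <- consolidate_records(recs)
  # identical match names cluster into one group here; force the two-group
  # pattern with GPS far apart instead
  recs2 <- suppressMessages(pool_sources(list(
    make_records("s1", "CS Fatick", lat = 14.0, lon = -16.0),
    make_records("s2", "Hôpital de Fatick", lat = 14.1, lon = -16.1)
  )))
  recs2$match_id <- c("FATICK-0001", "FATICK-0002")
  recs2$review_notes <- ""
  g2 <- consolidate_records(recs2)
  expect_equal(nrow(g2), 2)
  expect_match(g2$name_note[1], "GPS .* apart; treated as distinct")
  expect_match(g2$name_note[2], "FATICK-0001")

  # without GPS separation the note marks a candidate upgrade
  recs3 <- suppressMessages(pool_sources(list(
    make_records("s1", "CS Fatick"),
    make_records("s2", "Hôpital de Fatick")
  )))
  recs3$match_id <- c("FATICK-0001", "FATICK-0002")
  recs3$review_notes <- ""
  g3 <- consolidate_records(recs3)
  expect_match(g3$name_note[1], "candidate upgrade")
})

test_that("same name+type in different departments stays separate, noted", {
  recs <- suppressMessages(pool_sources(list(
    make_records("s1", "PS Mlomp", region = "Ziguinchor",
                 district = "Oussouye"),
    make_records("s2", "PS Mlomp", region = "Ziguinchor",
                 district = "Thionk Essyl")
  )))
  recs$match_id <- c("ZIGUINCHOR-0001", "ZIGUINCHOR-0002")
  recs$review_notes <- ""
  g <- consolidate_records(recs)
  expect_equal(nrow(g), 2)
  expect_match(g$name_note[1], "different department/district")
  expect_match(g$name_note[2], "kept separate")

  # unique names everywhere: zero name flags
  sim_groups <- consolidate_records(make_clustered(
    make_records("s1", "Keur Alpha"),
    make_records("s2", "Sinthiou Beta")
  ))
  expect_true(all(sim_groups$name_note == ""))
})

test_that("near-threshold group pairs land in the review report", {
  recs <- suppressMessages(pool_sources(list(
    make_records("s1", "Diakhao Sows"),
    make_records("s2", "Diakhao Mbodj")
  )))
  cand <- candidate_pairs(recs)
  clustered <- cluster_matches(recs, cand)
  d <- jaro_winkler_distance("diakhao sows", "diakhao mbodj")
  groups <- consolidate_records(clustered)
  report <- attr(groups, "review_report")
  if (d > 0.2 && d <= 0.3) {
    expect_equal(nrow(report), 1)
    expect_equal(report$jw_distance, d)
  } else {
    expect_equal(nrow(report), 0)
  }
})

test_that("the consolidated list has the documented schema and invariants", {
  sim <- small_sim(seed = 23)
  fit <- quiet_triangulate(sim$sources, sim$specs,
                           source_years = sim$source_years)
  cfl <- fit$cfl
  expect_equal(
    names(cfl),
    c("region", "match_id", "match_name", "group_fac_type",
      "group_latitude", "group_longitude", "group_gps_source", "n_gps",
      "n_source", "source_list", "data_flagged", "data_notes")
  )
  # one row per group, nothing lost from the pool
  expect_equal(nrow(cfl), length(unique(fit$full_list$match_id)))
  expect_setequal(cfl$match_id, fit$full_list$match_id)
  # flags exactly mirror notes
  expect_equal(cfl$data_flagged == 1, nzchar(cfl$data_notes))
  # type labels are written with spaces, never the raw codes
  expect_false(any(grepl("_", cfl$group_fac_type)))
  # n_source is the number of distinct contributing sources
  n_src <- tapply(fit$full_list$source_id, fit$full_list$match_id,
                  function(s) length(unique(s)))
  expect_equal(cfl$n_source, as.vector(n_src[cfl$match_id]))
})

test_that("consolidation is deterministic and idempotent", {
  sim <- small_sim(seed = 29)
  fit <- quiet_triangulate(sim$sources, sim$specs,
                           source_years = sim$source_years)
  again <- consolidate_records(
    fit$full_list, source_years = sim$source_years
  )
  expect_equal(build_cfl(again), fit$cfl, ignore_attr = TRUE)
  # re-flagging already-flagged groups does not duplicate notes
  reflagged <- flag_geo_conflicts(again, fit$full_list) |>
    flag_same_name_conflicts()
  expect_equal(build_cfl(reflagged), fit$cfl, ignore_attr = TRUE)
})

test_that("autre/unknown rows are carried but outside headline counts", {
  recs <- make_clustered(
    make_records("s1", "Hôpital Grand"),
    make_records("s2", "Clinique Privee Petite")
  )
  cfl <- build_cfl(consolidate_records(recs))
  expect_equal(nrow(cfl), 2)
  cov <- coverage_summary(cfl)
  expect_equal(cov$n_facilities[cov$region == "National" &
                                  cov$fac_type == "all"], 1)
})
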