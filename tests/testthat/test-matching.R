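test_that("jaro similarity matches hand-derived and boundary values", {
  expect_equal(jaro_similarity("abc", "abc"), 1)
  expect_equal(jaro_similarity("abc", "xyz"), 0)
  # classic worked example: m = 6, t = 1
  expect_equal(jaro_similarity("martha", "marhta"), 0.9444444, tolerance = 1e-6)
  expect_equal(jaro_similarity("", ""), 1)
  expect_equal(jaro_similarity("a", ""), 0)
})

test_that("jaro-winkler distance matches hand-derived values", {
  expect_equal(jaro_winkler_distance("nemataba", "nemataba"), 0)
  expect_equal(jaro_winkler_distance("abc", "xyz"), 1)
  # l = 3 common prefix: sim = 0.944444 + 0.3 * 0.055556
  expect_equal(jaro_winkler_distance("martha", "marhta"), 0.0388889,
               tolerance = 1e-6)
  cfg0 <- matching_config(prefix_weight = 0)
  expect_equal(1 - jaro_winkler_distance("martha", "marhta", cfg0),
               jaro_similarity("martha", "marhta"))
})

test_that("jaro agrees with the reference implementation on short strings", {
  strings <- all_strings(c("a", "b", "c"), 3)
  pairs <- expand.grid(s1 = strings, s2 = strings,
                       stringsAsFactors = FALSE)
  got <- jaro_similarity(pairs$s1, pairs$s2)
  want <- mapply(jaro_ref, pairs$s1, pairs$s2)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("jw distance is symmetric and zero only for identical strings", {
  set.seed(11)
  s1 <- replicate(300, random_string(letters[1:6], 8))
  s2 <- replicate(300, random_string(letters[1:6], 8))
  expect_equal(jaro_winkler_distance(s1, s2), jaro_winkler_distance(s2, s1))
  d <- jaro_winkler_distance(s1, s2)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d == 0, s1 == s2)
})

test_that("candidate generation blocks on region", {
  recs <- make_clustered(
    make_records("a", "PS Nemataba", region = "Kolda"),
    make_records("b", "Nemataba Poste de Santé", region = "Kolda")
  )
  cand <- candidate_pairs(recs)
  expect_equal(nrow(cand), 1)
  expect_true(cand$accepted)
  expect_equal(cand$jw_distance, 0)

  # identical names in different regions never meet
  cross <- suppressMessages(pool_sources(list(
    make_records("a", "PS Nemataba", region = "Kolda"),
    make_records("b", "PS Nemataba", region = "Fatick")
  )))
  expect_equal(nrow(candidate_pairs(cross)), 0)
})

test_that("a block of n identical names yields n(n-1)/2 accepted pairs", {
  n <- 6
  recs <- suppressMessages(pool_sources(purrr::map(seq_len(n), function(i) {
    make_records(paste0("s", i), "PS Ndiaye")
  })))
  cand <- candidate_pairs(recs)
  expect_equal(nrow(cand), n * (n - 1) / 2)
  expect_true(all(cand$accepted))
})

test_that("raising the threshold never loses accepted candidates", {
  sim <- small_sim(seed = 9)
  pooled <- suppressMessages(pool_sources(purrr::imap(
    sim$sources,
    function(tbl, sid) {
      suppressMessages(dedupe_within_source(normalize_records(
        suppressMessages(faclink:::records_from_table(tbl, sim$specs[[sid]]))
      )))
    }
  )))
  n_accepted <- purrr::map_int(c(0, 0.1, 0.2, 0.4), function(th) {
    sum(candidate_pairs(pooled, matching_config(threshold = th))$accepted)
  })
  expect_true(all(diff(n_accepted) >= 0))
})

test_that("clustering is transitive closure over accepted pairs", {
  recs <- make_clustered(
    make_records("a", "Saint Louis Alpha"),
    make_records("b", "Saint Louis Alphaa"),
    make_records("c", "Saint Louis Alphaaa")
  )
  # chained A-B, B-C must land in one group even if A-C alone is weaker
  cand <- candidate_pairs(recs)
  clustered <- cluster_matches(recs, cand)
  expect_equal(length(unique(clustered$match_id)), 1)

  # brute-force reachability gives the same partition
  acc <- cand[cand$accepted, ]
  ref <- closure_ref(recs$record_id, acc$record_a, acc$record_b)
  got <- split(clustered$record_id, clustered$match_id)
  expect_setequal(
    unname(purrr::map_chr(ref, ~ paste(sort(.x), collapse = "|"))),
    unname(purrr::map_chr(got, ~ paste(sort(.x), collapse = "|")))
  )
})

test_that("records with no accepted pair become singleton groups", {
  recs <- make_clustered(
    make_records("a", "Alpha Kanene"),
    make_records("b", "Zebra Mbodj")
  )
  expect_equal(length(unique(recs$match_id)), 2)
})

test_that("group ids are deterministic under record shuffling", {
  sim <- small_sim(seed = 5)
  fit <- quiet_triangulate(sim$sources, sim$specs,
                           source_years = sim$source_years)
  pooled <- fit$full_list[, setdiff(names(fit$full_list), "match_id")]
  set.seed(1)
  shuffled <- pooled[sample(nrow(pooled)), ]
  re <- cluster_matches(shuffled, candidate_pairs(shuffled))
  orig <- fit$full_list[order(fit$full_list$record_id), ]
  re <- re[order(re$record_id), ]
  expect_equal(re$match_id, orig$match_id)
})

test_that("clustering partitions the pool and respects region blocking", {
  sim <- small_sim(seed = 13)
  fit <- quiet_triangulate(sim$sources, sim$specs,
                           source_years = sim$source_years)
  full <- fit$full_list
  expect_equal(sum(table(full$match_id)), nrow(full))
  per_group_regions <- tapply(full$region_std, full$match_id,
                              function(r) length(unique(r)))
  expect_true(all(per_group_regions == 1))
})

test_that("review decisions split, merge, and replay idempotently", {
  recs <- make_clustered(
    make_records("a", "Keur Alpha"),
    make_records("b", "Sinthiou Beta"),
    make_records("c", "Sinthiou Betaa")
  )
  expect_equal(length(unique(recs$match_id)), 2)

  merged <- apply_review_decisions(recs, tibble::tibble(
    action = "merge", record_ref_a = "a:1", record_ref_b = "b:1",
    reason = "focal point confirms one facility"
  ))
  expect_equal(length(unique(merged$match_id)), 1)
  expect_match(merged$review_notes[merged$record_id == "a:1"],
               "focal point")

  split_back <- apply_review_decisions(merged, tibble::tibble(
    action = "split", record_ref_a = "c:1", record_ref_b = NA,
    reason = "different facility"
  ))
  expect_equal(length(unique(split_back$match_id)), 2)
  expect_equal(sum(table(split_back$match_id) == 1), 1)

  # empty decisions only add the (empty) notes column
  with_notes <- recs
  with_notes$review_notes <- ""
  expect_equal(apply_review_decisions(recs, NULL), with_notes)
  replay <- apply_review_decisions(split_back, tibble::tibble(
    action = "split", record_ref_a = "c:1", record_ref_b = NA,
    reason = "different facility"
  ))
  expect_equal(replay, split_back)
  expect_error(
    apply_review_decisions(recs, tibble::tibble(
      action = "merge", record_ref_a = "a:1", record_ref_b = "zz:9",
      reason = "x"
    )),
    "zz:9"
  )
})
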