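#' Fuzzy-matching configuration
#'
#' Controls candidate generation: the Jaro-Winkler *distance* threshold (a
#' pair is a candidate match when distance <= threshold, i.e. similarity >=
#' 1 - threshold), the Winkler prefix weight `p` and prefix cap, and the
#' blocking attribute (region by default — no cross-region pairs are ever
#' generated automatically).
#'
#' @param threshold Maximum Jaro-Winkler distance for an accepted pair.
#'   Default 0.2.
#' @param prefix_weight Winkler prefix weight p, in \[0, 0.25\]. Default 0.1.
#' @param prefix_max Maximum common-prefix length rewarded. Default 4.
#' @param block_key Column used for blocking. Default `"region_std"`.
#' @return A list with class `"matching_config"`.
#' @export
matching_config <- function(threshold = 0.2, prefix_weight = 0.1,
                            prefix_max = 4L, block_key = "region_std") {
  stopifnot(
    threshold >= 0, threshold <= 1,
    prefix_weight >= 0, prefix_weight <= 0.25,
    prefix_max >= 0
  )
  structure(
    list(
      threshold = threshold,
      prefix_weight = prefix_weight,
      prefix_max = as.integer(prefix_max),
      block_key = block_key
    ),
    class = "matching_config"
  )
}

#' Jaro similarity
#'
#' Standard Jaro string similarity in \[0, 1\]: with `m` characters matching
#' within a window of `floor(max(|s1|, |s2|) / 2) - 1` and `t` half the
#' number of transpositions, returns `(m/|s1| + m/|s2| + (m - t)/m) / 3`
#' (0 when `m = 0`; 1 when both strings are empty). Vectorized over pairs;
#' compares Unicode code points.
#'
#' @param s1,s2 Character vectors of equal length (or length 1, recycled).
#' @return Numeric vector of similarities.
#' @examples
#' jaro_similarity("martha", "marhta")
#' @export
jaro_similarity <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  jaro_sim_cpp(rep_len(enc2utf8(as.character(s1)), n),
               rep_len(enc2utf8(as.character(s2)), n))
}

#' Jaro-Winkler distance
#'
#' One minus the Jaro-Winkler similarity
#' `jaro + l * p * (1 - jaro)`, where `l` is the common-prefix length capped
#' at `cfg$prefix_max`. Symmetric; 0 exactly for identical strings (for
#' `p < 0.25`).
#'
#' @param s1,s2 Character vectors (recycled to a common length).
#' @param cfg A [matching_config()] supplying `prefix_weight` and
#'   `prefix_max`.
#' @return Numeric vector of distances in \[0, 1\].
#' @examples
#' jaro_winkler_distance("martha", "marhta")
#' @export
jaro_winkler_distance <- function(s1, s2, cfg = matching_config()) {
  n <- max(length(s1), length(s2))
  1 - jaro_winkler_sim_cpp(
    rep_len(enc2utf8(as.character(s1)), n),
    rep_len(enc2utf8(as.character(s2)), n),
    cfg$prefix_weight, cfg$prefix_max
  )
}

#' Generate within-block candidate pairs
#'
#' Emits every unordered pair of records sharing a block key (canonical
#' region by default) with its Jaro-Winkler distance on `match_name`, marking
#' pairs at or under the threshold as accepted. Records with a missing block
#' key form their own singleton block and are never paired automatically.
#'
#' @param records Pooled normalized records with `record_id` and
#'   `match_name`.
#' @param cfg A [matching_config()].
#' @return Tibble with columns `record_a`, `record_b`, `jw_distance`,
#'   `accepted`, `review_reason`.
#' @export
candidate_pairs <- function(records, cfg = matching_config()) {
  stopifnot(all(c("record_id", "match_name", cfg$block_key) %in%
                  names(records)))
  empty <- tibble::tibble(
    record_a = character(), record_b = character(),
    jw_distance = numeric(), accepted = logical(),
    review_reason = character()
  )
  if (nrow(records) < 2) return(empty)

  blocks <- split(
    seq_len(nrow(records)),
    records[[cfg$block_key]],
    drop = TRUE
  )
  blocks <- blocks[lengths(blocks) >= 2]
  if (!length(blocks)) return(empty)

  pairs <- purrr::map(blocks, function(idx) {
    # stable record order inside the block so output is shuffle-invariant
    idx <- idx[order(records$record_id[idx])]
    cmb <- combn(idx, 2)
    tibble::tibble(
      record_a = records$record_id[cmb[1, ]],
      record_b = records$record_id[cmb[2, ]],
      name_a = records$match_name[cmb[1, ]],
      name_b = records$match_name[cmb[2, ]]
    )
  }) |>
    purrr::list_rbind()

  pairs |>
    dplyr::mutate(
      jw_distance = jaro_winkler_distance(.data$name_a, .data$name_b, cfg),
      accepted = .data$jw_distance <= cfg$threshold,
      review_reason = NA_character_
    ) |>
    dplyr::select(-"name_a", -"name_b") |>
    dplyr::arrange(.data$record_a, .data$record_b)
}

# deterministic match ids: groups ordered by region, then lexicographic
# minimum match_name, then earliest (source_id, row_index)
assign_match_ids <- function(records, membership) {
  ord_key <- order(records$source_id, records$row_index)
  source_rank <- integer(nrow(records))
  source_rank[ord_key] <- seq_len(nrow(records))

  grp <- tibble::tibble(
    component = membership,
    region = dplyr::coalesce(records$region_std, "ZZ missing region"),
    name = records$match_name,
    srank = source_rank
  ) |>
    dplyr::summarise(
      region = min(.data$region),
      min_name = min(.data$name),
      min_srank = min(.data$srank),
      .by = "component"
    ) |>
    dplyr::arrange(.data$region, .data$min_name, .data$min_srank) |>
    dplyr::mutate(
      region_slug = toupper(gsub("[^A-Za-z0-9]+", "", .data$region))
    )
  grp <- grp |>
    dplyr::mutate(seq_in_region = dplyr::row_number(), .by = "region_slug") |>
    dplyr::mutate(match_id = sprintf("%s-%04d", .data$region_slug,
                                     .data$seq_in_region))
  grp$match_id[match(membership, grp$component)]
}

#' Cluster accepted matches into facility groups
#'
#' Single-linkage transitive closure: records connected by any chain of
#' accepted candidate pairs form one match group (connected components of
#' the acceptance graph); unmatched records become singleton groups. Each
#' group receives a deterministic `match_id` (region slug + zero-padded
#' index, ordered by region, then minimum match name, then source order), so
#' shuffling the input changes nothing.
#'
#' @param records Pooled normalized records with `record_id`.
#' @param candidates Candidate tibble from [candidate_pairs()]; only rows
#'   with `accepted == TRUE` link records.
#' @return The records tibble with a `match_id` column added.
#' @export
cluster_matches <- function(records, candidates) {
  stopifnot("record_id" %in% names(records))
  acc <- candidates[candidates$accepted %in% TRUE, , drop = FALSE]
  unknown <- setdiff(c(acc$record_a, acc$record_b), records$record_id)
  if (length(unknown)) {
    stop("candidates reference unknown record(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    acc[, c("record_a", "record_b")],
    directed = FALSE,
    vertices = data.frame(name = records$record_id)
  )
  membership <- igraph::components(g)$membership[records$record_id]
  records$match_id <- assign_match_ids(records, membership)
  records
}

#' Apply manual review decisions
#'
#' Applies split/merge corrections from manual verification to clustered
#' records. A `split` moves `record_ref_a` into its own group; a `merge`
#' unions the groups containing `record_ref_a` and `record_ref_b`. Each
#' action appends its reason to the affected records' `review_notes`
#' (deduplicated, so re-application is idempotent), and match ids are
#' recomputed deterministically afterwards.
#'
#' @param records Clustered records (with `match_id`).
#' @param decisions Tibble/data frame with columns `action` (`"split"` or
#'   `"merge"`), `record_ref_a`, `record_ref_b` (ignored for splits),
#'   `reason`.
#' @return Records with updated `match_id` and `review_notes`.
#' @export
apply_review_decisions <- function(records, decisions) {
  if (!"review_notes" %in% names(records)) {
    records$review_notes <- ""
  }
  if (is.null(decisions) || nrow(decisions) == 0) return(records)
  stopifnot(all(c("action", "record_ref_a") %in% names(decisions)))

  add_note <- function(notes, idx, note) {
    for (i in idx) {
      existing <- strsplit(notes[i], "; ", fixed = TRUE)[[1]]
      if (!note %in% existing) {
        notes[i] <- paste(c(existing[nzchar(existing)], note),
                          collapse = "; ")
      }
    }
    notes
  }

  group <- records$match_id
  next_tmp <- 0L
  for (k in seq_len(nrow(decisions))) {
    d <- decisions[k, ]
    ia <- match(d$record_ref_a, records$record_id)
    if (is.na(ia)) {
      stop("review decision ", k, " references unknown record: ",
           d$record_ref_a)
    }
    if (d$action == "split") {
      members <- which(group == group[ia])
      if (length(members) > 1) {
        next_tmp <- next_tmp + 1L
        group[ia] <- paste0(".split", next_tmp)
      }
      records$review_notes <- add_note(
        records$review_notes, ia,
        paste0("review split: ", d$reason %||% "")
      )
    } else if (d$action == "merge") {
      ib <- match(d$record_ref_b, records$record_id)
      if (is.na(ib)) {
        stop("review decision ", k, " references unknown record: ",
             d$record_ref_b)
      }
      members <- which(group %in% c(group[ia], group[ib]))
      group[members] <- group[ia]
      records$review_notes <- add_note(
        records$review_notes, c(ia, ib),
        paste0("review merge: ", d$reason %||% "")
      )
    } else {
      stop("unknown review action: ", d$action)
    }
  }
  records$match_id <- assign_match_ids(
    records, match(group, unique(group))
  )
  records
}
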