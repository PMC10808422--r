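# Independent reference implementations used as oracles. Deliberately plain
# R with explicit loops, sharing no code with the package internals.

# textbook Jaro similarity: matching-character flags within the window,
# then transpositions among matched characters
jaro_ref <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  window <- max(floor(max(la, lb) / 2) - 1, 0)
  amatch <- logical(la); bmatch <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - window)
    hi <- min(lb, i + window)
    if (hi < lo) next
    for (j in lo:hi) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] <- TRUE
        bmatch[j] <- TRUE
        break
      }
    }
  }
  m <- sum(amatch)
  if (m == 0) return(0)
  ta <- a[amatch]
  tb <- b[bmatch]
  t <- sum(ta != tb) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

jaro_winkler_ref <- function(s1, s2, p = 0.1, lmax = 4) {
  sim <- jaro_ref(s1, s2)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  l <- 0
  for (k in seq_len(min(length(a), length(b), lmax))) {
    if (a[k] != b[k]) break
    l <- k
  }
  1 - (sim + l * p * (1 - sim))
}

# spherical law of cosines, an algebraically different great-circle formula
slc_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) *
      cos((lon2 - lon1) * to_rad)
  R * acos(pmin(1, pmax(-1, d)))
}

# pairwise linkage metrics by a double loop over all record pairs
pairwise_metrics_ref <- function(pred, truth) {
  ids <- pred$record_id
  n <- length(ids)
  grp <- pred$match_id[match(ids, pred$record_id)]
  ent <- truth$facility_id[match(ids, truth$record_id)]
  n_pred <- 0; n_true <- 0; n_both <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        same_g <- grp[i] == grp[j]
        same_e <- ent[i] == ent[j]
        n_pred <- n_pred + same_g
        n_true <- n_true + same_e
        n_both <- n_both + (same_g && same_e)
      }
    }
  }
  precision <- if (n_pred == 0) 1 else n_both / n_pred
  recall <- if (n_true == 0) 1 else n_both / n_true
  list(
    n_pred_pairs = n_pred, n_true_pairs = n_true, n_common_pairs = n_both,
    precision = precision, recall = recall
  )
}

# transitive closure by brute-force reachability (repeated expansion)
closure_ref <- function(ids, pairs_a, pairs_b) {
  comp <- seq_along(ids)
  names(comp) <- ids
  repeat {
    changed <- FALSE
    for (k in seq_along(pairs_a)) {
      ca <- comp[[pairs_a[k]]]
      cb <- comp[[pairs_b[k]]]
      if (ca != cb) {
        comp[comp == cb] <- ca
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, comp)
}

# all strings over an alphabet up to a maximum length
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste0, collapse = ""))
  }
  out
}

random_string <- function(alphabet, max_len) {
  paste0(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
         collapse = "")
}
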