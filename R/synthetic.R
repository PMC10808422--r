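FRENCH_TYPE_LABEL <- c(
  hopital = "Hôpital",
  centre_de_sante = "Centre de Santé",
  poste_de_sante = "Poste de Santé",
  case_de_sante = "Case de Santé",
  autre = "Clinique",
  unknown = NA_character_
)

# toponym fragments: generic Senegalese-sounding pieces, no real facility
# names
NAME_PREFIXES <- c(
  "Keur", "Medina", "Ndame", "Touba", "Sam", "Thiawene", "Darou", "Sare",
  "Sinthiou", "Ndiaga", "Mbour", "Diama", "Ngui", "Bala", "Koussanar",
  "Niandane", "Saint", "Velingara", "Goudomp", "Oussou", "Pata", "Diende",
  "Bambey", "Ndofane", "Loul", "Sessene", "Tattaguine", "Niakhar", "Fimela",
  "Palmarin", "Djilor", "Toubacouta", "Sokone", "Karang", "Passy",
  "Foundiougne", "Gandiaye", "Wack", "Porokhane", "Taiba", "Kahone",
  "Ndoffane", "Paoskoto", "Nioro", "Kayemor", "Dabaly", "Khelcom",
  "Colobane", "Gossas", "Mbar", "Diakhao", "Diofior", "Loudia", "Mlomp",
  "Kafountine", "Diouloulou", "Tenghori", "Niaguis", "Adeane", "Boutoupa",
  "Tanaff", "Marsassoum", "Bounkiling", "Diattacounda", "Samine",
  "Diannah", "Kolibantang", "Koumbacara", "Dabo", "Mampatim", "Dioulacolon",
  "Salikegne", "Kounkane", "Wassadou", "Dialambere", "Bagadadji",
  "Coumbacara", "Nganda", "Missirah", "Maka", "Ndoga", "Bandafassi",
  "Fongolimbi", "Salemata"
)
NAME_SUFFIXES <- c(
  "Ndiaye", "Diop", "Fall", "Sow", "Ba", "Diallo", "Gueye", "Seck", "Faye",
  "Sarr", "Thiam", "Ndour", "Sylla", "Camara", "Toure", "Cisse", "Kane",
  "Niang", "Mbaye", "Samb", "Diouf", "Goumbala", "Wade", "Beye", "Ly",
  "Dieng", "Tall", "Sene", "Badji", "Sagna", "Coly", "Mane", "Sane", "Sonko",
  "Gassama", "Dabo", "Balde", "Barry", "Kande", "Dramé", "Konate", "Keita",
  "Souare", "Sakho", "Sidibe", "Diedhiou", "Goudiaby", "Diatta", "Dieme",
  "Bodian", "Tamba", "Dansokho", "Cissokho", "Damba", "Sadiakhou", "Baldeh",
  "Kante", "Fofana", "Sabaly", "Mballo"
)

#' Synthetic registry configuration
#'
#' Parameters of the ground-truthed facility universe and of the K noisy
#' overlapping source lists drawn from it. Defaults describe the reference
#' simulation used throughout the package's tests: 500 facilities over
#' Senegal's 14 regions with the national type mix (about 2% hospitals, 5%
#' health centers, 50% health posts, 43% health huts), observed by 5 sources
#' with mild name noise, partial GPS coverage, and metre-to-km-scale GPS
#' jitter.
#'
#' @param seed Integer seed; fully determines all output.
#' @param n_facilities Number of true facilities in the universe.
#' @param n_regions Number of regions used (first `n_regions` of
#'   [senegal_regions()]).
#' @param type_mix Named probabilities over the four pyramid types.
#' @param n_sources Number of source lists (ids follow the GPS hierarchy:
#'   cous, spa2016, spa2017, esri, hdx, maina, ansd, msas, ...).
#' @param inclusion_prob Probability a source observes a facility.
#' @param gps_prob Probability an observed record carries coordinates.
#' @param gps_jitter_sd_m Isotropic GPS noise standard deviation in metres,
#'   applied per axis and converted to degrees at the local latitude.
#' @param name_noise Named probabilities for the name error modes: `typo`
#'   (one character edit), `accent` (accent added to an "e"), `type_prefix`
#'   (type token attached to the name), `acronym` ("Saint" contracted to
#'   "St."), `roman` (terminal number written as a roman numeral).
#' @param upgrade_prob Probability a post/center/hospital was upgraded from
#'   the next-lower type during the observation window, so earlier-dated
#'   sources report the lower type.
#' @param within_source_dup_prob Probability a record is duplicated inside
#'   its source (the duplicate loses its GPS).
#' @param min_name_separation Minimum Jaro-Winkler distance enforced between
#'   distinct true facility names within a region, so ground-truth entities
#'   are separable in principle at the default matching threshold.
#' @return A list with class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_facilities = 500L,
    n_regions = 14L,
    type_mix = c(hopital = 0.02, centre_de_sante = 0.05,
                 poste_de_sante = 0.50, case_de_sante = 0.43),
    n_sources = 5L,
    inclusion_prob = 0.75,
    gps_prob = 0.7,
    gps_jitter_sd_m = 150,
    name_noise = c(typo = 0.04, accent = 0.15, type_prefix = 0.5,
                   acronym = 0.3, roman = 0.3),
    upgrade_prob = 0.1,
    within_source_dup_prob = 0.01,
    min_name_separation = 0.28) {
  probs <- c(inclusion_prob, gps_prob, upgrade_prob, within_source_dup_prob,
             name_noise, type_mix)
  stopifnot(
    all(probs >= 0), all(probs <= 1),
    abs(sum(type_mix) - 1) < 1e-6,
    n_regions >= 1, n_regions <= length(senegal_regions()),
    gps_jitter_sd_m >= 0
  )
  structure(
    list(
      seed = as.integer(seed),
      n_facilities = as.integer(n_facilities),
      n_regions = as.integer(n_regions),
      type_mix = type_mix,
      n_sources = as.integer(n_sources),
      inclusion_prob = inclusion_prob,
      gps_prob = gps_prob,
      gps_jitter_sd_m = gps_jitter_sd_m,
      name_noise = name_noise,
      upgrade_prob = upgrade_prob,
      within_source_dup_prob = within_source_dup_prob,
      min_name_separation = min_name_separation
    ),
    class = "synthetic_config"
  )
}

# source ids follow the GPS-preference vocabulary so the default hierarchy
# engages; years give the recency structure type upgrades need
SYNTH_SOURCE_POOL <- c(
  cous = 2019L, spa2016 = 2016L, spa2017 = 2017L, esri = 2020L, hdx = 2021L,
  maina = 2019L, ansd = 2013L, msas = 2022L, spa2015 = 2015L, spa2014 = 2014L,
  reglist1 = 2022L, reglist2 = 2023L
)

# region bounding boxes: a deterministic 7x2 grid over Senegal's extent
region_boxes <- function(n_regions) {
  regions <- senegal_regions()[seq_len(n_regions)]
  lat0 <- 12.5; lat1 <- 16.5; lon0 <- -17.3; lon1 <- -11.5
  ncol_grid <- 7
  idx <- seq_along(regions) - 1L
  row <- idx %/% ncol_grid
  col <- idx %% ncol_grid
  tibble::tibble(
    region = regions,
    lat_min = lat0 + row * (lat1 - lat0) / 2,
    lat_max = lat0 + (row + 1) * (lat1 - lat0) / 2,
    lon_min = lon0 + col * (lon1 - lon0) / ncol_grid,
    lon_max = lon0 + (col + 1) * (lon1 - lon0) / ncol_grid
  )
}

#' Generate a ground-truth facility universe
#'
#' Draws `n_facilities` facilities with plausible toponym-fragment names
#' (unique and well separated within each region), a region, a facility
#' type from the configured mix, coordinates inside per-region bounding
#' boxes, a department, and optional upgrade events (`pre_type` reported by
#' sources dated before `upgrade_year`). Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble of true facilities: `facility_id`, `region`, `department`,
#'   `fac_name`, `fac_type`, `pre_type`, `upgrade_year`, `latitude`,
#'   `longitude`.
#' @export
generate_universe <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  boxes <- region_boxes(cfg$n_regions)
  regions <- boxes$region

  region <- sample(regions, cfg$n_facilities, replace = TRUE)
  fac_type <- sample(names(cfg$type_mix), cfg$n_facilities, replace = TRUE,
                     prob = cfg$type_mix)

  # names: prefix-suffix fragment pairs, unique within region. Preference
  # order keeps ground-truth entities separable at the matching threshold:
  # unique prefixes and full separation first, then separation only, then
  # any unused combination (only reached at very large region sizes).
  grid <- expand.grid(p = NAME_PREFIXES, s = NAME_SUFFIXES,
                      stringsAsFactors = FALSE)
  grid_names <- paste(grid$p, grid$s)
  grid_keys <- normalize_name(grid_names, normalization_lexicon())
  names_out <- character(cfg$n_facilities)
  for (r in regions) {
    idx <- which(region == r)
    if (!length(idx)) next
    perm <- sample(nrow(grid))
    accepted <- integer(0)
    keys <- character(0)
    used_prefix <- character(0)
    for (pass in 1:3) {
      for (g in perm) {
        if (length(accepted) == length(idx)) break
        if (g %in% accepted) next
        if (pass == 1 && grid$p[g] %in% used_prefix) next
        if (pass <= 2 && length(keys) &&
            min(jaro_winkler_distance(grid_keys[g], keys)) <=
              cfg$min_name_separation) next
        accepted <- c(accepted, g)
        keys <- c(keys, grid_keys[g])
        used_prefix <- c(used_prefix, grid$p[g])
      }
      if (length(accepted) == length(idx)) break
    }
    nm <- grid_names[accepted]
    if (length(accepted) < length(idx)) {
      # region larger than the fragment grid: number extra reuses
      extra <- length(idx) - length(accepted)
      nm <- c(nm, paste(grid_names[perm[seq_len(extra)]],
                        20 + seq_len(extra)))
    }
    numbered <- runif(length(idx)) < 0.12
    nm[numbered] <- paste(nm[numbered],
                          sample(2:4, sum(numbered), replace = TRUE))
    names_out[idx] <- nm
  }

  ladder <- facility_types(ladder_only = TRUE)
  rank <- match(fac_type, ladder)
  upgraded <- runif(cfg$n_facilities) < cfg$upgrade_prob & rank > 1
  pre_type <- ifelse(upgraded, ladder[pmax(rank - 1, 1)], fac_type)
  upgrade_year <- ifelse(upgraded, sample(2015:2021, cfg$n_facilities,
                                          replace = TRUE), NA_integer_)

  b <- boxes[match(region, boxes$region), ]
  tibble::tibble(
    facility_id = sprintf("F%04d", seq_len(cfg$n_facilities)),
    region = region,
    department = paste(region, "Dept", sample(1:3, cfg$n_facilities,
                                              replace = TRUE)),
    fac_name = names_out,
    fac_type = fac_type,
    pre_type = pre_type,
    upgrade_year = as.integer(upgrade_year),
    latitude = runif(cfg$n_facilities, b$lat_min, b$lat_max),
    longitude = runif(cfg$n_facilities, b$lon_min, b$lon_max)
  )
}

apply_typo <- function(nm) {
  chars <- strsplit(nm, "")[[1]]
  n <- length(chars)
  if (n < 4) return(nm)
  pos <- sample(seq_len(n), 1)
  op <- sample(c("sub", "del", "swap"), 1)
  if (op == "sub") {
    chars[pos] <- sample(letters, 1)
  } else if (op == "del") {
    chars <- chars[-pos]
  } else {
    p2 <- if (pos == n) pos - 1L else pos
    tmp <- chars[p2]; chars[p2] <- chars[p2 + 1]; chars[p2 + 1] <- tmp
  }
  paste(chars, collapse = "")
}

attach_type_token <- function(nm, type) {
  pick <- function(x) x[[sample(length(x), 1)]]
  switch(type,
    poste_de_sante = pick(list(
      paste("PS", nm), paste("Poste de Santé", nm),
      paste(nm, "Poste de Santé")
    )),
    centre_de_sante = pick(list(
      paste("CS", nm), paste("Centre de Santé", nm)
    )),
    case_de_sante = pick(list(
      paste("Case de Santé", nm), paste("CDS", nm)
    )),
    hopital = pick(list(
      paste("Hôpital", nm), paste("Hôpital de", nm)
    )),
    nm
  )
}

noisy_name <- function(nm, type, noise) {
  if (runif(1) < noise[["typo"]]) nm <- apply_typo(nm)
  if (runif(1) < noise[["accent"]] && grepl("e", nm)) {
    pos <- sample(gregexpr("e", nm)[[1]], 1)
    substr(nm, pos, pos) <- "é"
  }
  if (runif(1) < noise[["acronym"]] && startsWith(nm, "Saint ")) {
    nm <- sub("^Saint ", "St. ", nm)
  }
  if (runif(1) < noise[["roman"]] && grepl(" ([2-9]|1[0-9]|20)$", nm)) {
    num <- as.integer(sub(".* ", "", nm))
    nm <- sub(" [0-9]+$", paste0(" ", toupper(ROMAN_NUMERALS[num])), nm)
  }
  if (runif(1) < noise[["type_prefix"]]) {
    nm <- attach_type_token(nm, type)
  }
  nm
}

#' Emit noisy overlapping source lists
#'
#' Draws `cfg$n_sources` source lists from a universe. Each source includes
#' facilities independently at the inclusion probability, reports the
#' facility type as of its source year (sources dated before an upgrade
#' report the pre-upgrade type; the explicit type column is sometimes left
#' blank so name-based inference is exercised), perturbs names with the
#' configured error modes, jitters coordinates by isotropic metre-scale
#' noise, drops GPS at `1 - gps_prob`, and injects exact within-source
#' duplicate rows (without GPS). Row order is shuffled per source.
#' Deterministic under `cfg$seed`.
#'
#' @param universe Output of [generate_universe()].
#' @param cfg The same [synthetic_config()].
#' @return List: `sources` (named list of raw tibbles with French headers),
#'   `specs` (named list of [source_spec()]), `source_years` (named
#'   vector), `truth` (tibble `record_id`, `source_id`, `row_index`,
#'   `facility_id`).
#' @export
emit_source_lists <- function(universe, cfg = synthetic_config()) {
  set.seed(cfg$seed + 1L)
  ids <- names(SYNTH_SOURCE_POOL)
  if (cfg$n_sources > length(ids)) {
    extra <- sprintf("extra%02d", seq_len(cfg$n_sources - length(ids)))
    pool <- c(SYNTH_SOURCE_POOL,
              setNames(rep(2022L, length(extra)), extra))
  } else {
    pool <- SYNTH_SOURCE_POOL
  }
  source_ids <- names(pool)[seq_len(cfg$n_sources)]
  years <- pool[source_ids]

  sources <- list()
  truth <- list()
  for (sid in source_ids) {
    yr <- years[[sid]]
    keep <- runif(nrow(universe)) < cfg$inclusion_prob
    u <- universe[keep, , drop = FALSE]
    if (nrow(u) == 0) {
      sources[[sid]] <- tibble::tibble(
        nom = character(), type = character(), region = character(),
        departement = character(), latitude = numeric(),
        longitude = numeric()
      )
      truth[[sid]] <- tibble::tibble(
        record_id = character(), source_id = character(),
        row_index = integer(), facility_id = character()
      )
      next
    }
    reported_type <- ifelse(
      !is.na(u$upgrade_year) & yr < u$upgrade_year, u$pre_type, u$fac_type
    )
    nm <- purrr::map2_chr(u$fac_name, reported_type,
                          ~ noisy_name(.x, .y, cfg$name_noise))
    type_txt <- ifelse(runif(nrow(u)) < 0.7,
                       FRENCH_TYPE_LABEL[reported_type], NA_character_)
    has_gps <- runif(nrow(u)) < cfg$gps_prob
    dn <- rnorm(nrow(u), 0, cfg$gps_jitter_sd_m)
    de <- rnorm(nrow(u), 0, cfg$gps_jitter_sd_m)
    lat <- u$latitude + dn / 111320
    lon <- u$longitude + de / (111320 * cos(u$latitude * pi / 180))
    tbl <- tibble::tibble(
      nom = nm,
      type = unname(type_txt),
      region = u$region,
      departement = u$department,
      latitude = ifelse(has_gps, lat, NA_real_),
      longitude = ifelse(has_gps, lon, NA_real_),
      .facility_id = u$facility_id
    )
    dup <- runif(nrow(tbl)) < cfg$within_source_dup_prob
    if (any(dup)) {
      dup_rows <- tbl[dup, , drop = FALSE]
      dup_rows$latitude <- NA_real_
      dup_rows$longitude <- NA_real_
      tbl <- dplyr::bind_rows(tbl, dup_rows)
    }
    tbl <- tbl[sample(nrow(tbl)), , drop = FALSE]
    truth[[sid]] <- tibble::tibble(
      record_id = paste(sid, seq_len(nrow(tbl)), sep = ":"),
      source_id = sid,
      row_index = seq_len(nrow(tbl)),
      facility_id = tbl$.facility_id
    )
    sources[[sid]] <- dplyr::select(tbl, -".facility_id")
  }

  specs <- purrr::imap(sources, function(tbl, sid) {
    source_spec(
      sid,
      column_map = c(name = "nom", type = "type", region = "region",
                     department = "departement", latitude = "latitude",
                     longitude = "longitude"),
      source_year = years[[sid]]
    )
  })

  list(
    sources = sources,
    specs = specs,
    source_years = years,
    truth = purrr::list_rbind(truth)
  )
}

#' Simulate a multi-source facility registry
#'
#' Convenience wrapper: [generate_universe()] then [emit_source_lists()].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `universe`, `sources`, `specs`, `source_years`,
#'   `truth`, and the `config` used.
#' @examples
#' sim <- simulate_registry(synthetic_config(seed = 7, n_facilities = 50,
#'                                           n_sources = 3))
#' names(sim$sources)
#' @export
simulate_registry <- function(cfg = synthetic_config()) {
  universe <- generate_universe(cfg)
  emitted <- emit_source_lists(universe, cfg)
  c(list(universe = universe, config = cfg), emitted)
}

#' Write a simulated registry to disk
#'
#' Writes one CSV per source, the ground-truth map, and a YAML run
#' configuration (column maps, years, GPS hierarchy) that
#' [read_run_config()] can read back.
#'
#' @param sim Output of [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_sources <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$sources)) {
    readr::write_csv(sim$sources[[sid]], file.path(dir, paste0(sid, ".csv")))
  }
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  cfg <- list(
    sources = purrr::map(sim$specs, function(sp) {
      list(column_map = as.list(sp$column_map), year = sp$source_year)
    }),
    hierarchy = source_hierarchy()$tiers
  )
  yaml::write_yaml(cfg, file.path(dir, "run_config.yml"))
  invisible(dir)
}
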