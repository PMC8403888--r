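recovery_columns <- c("sample_accession", "key", "ord", "kind", "value",
                      "latitude", "longitude", "dialect", "zero_zero",
                      "year", "precision", "range_end_year")

empty_recoveries <- function() {
  tibble::tibble(sample_accession = character(), key = character(),
                 ord = integer(), kind = character(), value = character(),
                 latitude = double(), longitude = double(),
                 dialect = character(), zero_zero = logical(),
                 year = integer(), precision = character(),
                 range_end_year = integer())
}

#' Scan non-canonical attributes for misfiled coordinates and dates
#'
#' Submitters sometimes deposit coordinates or dates under the wrong key
#' (`"41.40 N 2.17 E"` in `isolation_source`, a year buried in a
#' `description`). Every attribute value under a key *not* in the canonical
#' key sets is tested first as a coordinate, then (if that fails) as a
#' date; successes are returned in attribute order. Scanning never
#' overwrites canonical parses -- promotion into empty canonical slots
#' happens in [parse_sample()]/[parse_corpus()].
#'
#' @param attributes attribute tibble (columns `sample_accession` optional,
#'   `key`, `value`, `ord`).
#' @param config a [parser_config()].
#' @return tibble of recoveries: `key`, `ord`, `kind` (`"coordinate"` or
#'   `"temporal"`), `value`, and the parsed fields.
#' @export
scan_misfiled <- function(attributes, config = parser_config()) {
  attrs <- tibble::as_tibble(attributes)
  if (!"sample_accession" %in% names(attrs)) attrs$sample_accession <- "sample"
  scan_misfiled_table(attrs, config)
}

scan_misfiled_table <- function(attrs, config) {
  non_canon <- attrs[!attrs$key %in% canonical_keys(config), , drop = FALSE]
  if (!nrow(non_canon)) return(empty_recoveries())
  pc <- parse_lat_lon(non_canon$value, config$placeholder_tokens)
  is_coord <- !is.na(pc$latitude)
  coord_rec <- dplyr::bind_cols(
    non_canon[is_coord, c("sample_accession", "key", "ord", "value")],
    pc[is_coord, c("latitude", "longitude", "dialect", "zero_zero")])
  coord_rec$kind <- rep("coordinate", nrow(coord_rec))
  coord_rec$year <- NA_integer_
  coord_rec$precision <- NA_character_
  coord_rec$range_end_year <- NA_integer_
  rest <- non_canon[!is_coord, , drop = FALSE]
  pd <- parse_collection_date(rest$value, config$placeholder_tokens)
  is_temp <- !is.na(pd$year)
  temp_rec <- dplyr::bind_cols(
    rest[is_temp, c("sample_accession", "key", "ord", "value")],
    pd[is_temp, c("year", "precision", "range_end_year")])
  temp_rec$kind <- rep("temporal", nrow(temp_rec))
  temp_rec$latitude <- NA_real_
  temp_rec$longitude <- NA_real_
  temp_rec$dialect <- NA_character_
  temp_rec$zero_zero <- FALSE
  dplyr::bind_rows(coord_rec, temp_rec) |>
    dplyr::arrange(.data$sample_accession, .data$ord) |>
    dplyr::select(dplyr::all_of(recovery_columns))
}

# parse every sample's attributes; one vectorized pass shared by
# parse_sample() and parse_corpus() so the two can never diverge
parse_attr_table <- function(attrs, sample_ids, config) {
  base <- tibble::tibble(sample_accession = sample_ids)

  # canonical combined lat/lon keys, first parseable value per sample;
  # later parseable duplicates become recoveries (extra candidates)
  coord_rows <- attrs[attrs$key %in% config$coord_keys, , drop = FALSE]
  coord_extra <- empty_recoveries()
  if (nrow(coord_rows)) {
    pc <- parse_lat_lon(coord_rows$value, config$placeholder_tokens)
    cr <- dplyr::bind_cols(
      coord_rows[, c("sample_accession", "key", "ord", "value")],
      pc[, c("latitude", "longitude", "dialect", "zero_zero")])
    ok <- cr[!is.na(cr$latitude), , drop = FALSE] |>
      dplyr::arrange(.data$sample_accession, .data$ord) |>
      dplyr::group_by(.data$sample_accession) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
    coord_canon <- ok[ok$rank == 1, , drop = FALSE]
    extra <- ok[ok$rank > 1, , drop = FALSE]
    if (nrow(extra)) {
      extra$kind <- "coordinate"
      extra$year <- NA_integer_
      extra$precision <- NA_character_
      extra$range_end_year <- NA_integer_
      coord_extra <- extra[, recovery_columns]
    }
  } else {
    coord_canon <- NULL
  }

  # split latitude/longitude fields for samples without a combined value
  split_canon <- NULL
  lat_rows <- attrs[attrs$key %in% config$lat_keys, , drop = FALSE]
  lon_rows <- attrs[attrs$key %in% config$lon_keys, , drop = FALSE]
  if (nrow(lat_rows) && nrow(lon_rows)) {
    first_of <- function(d) d |>
      dplyr::arrange(.data$sample_accession, .data$ord) |>
      dplyr::distinct(.data$sample_accession, .keep_all = TRUE)
    pair <- dplyr::inner_join(
      first_of(lat_rows)[, c("sample_accession", "key", "value", "ord")],
      first_of(lon_rows)[, c("sample_accession", "key", "value", "ord")],
      by = "sample_accession", suffix = c("_lat", "_lon"))
    if (nrow(pair)) {
      ps <- parse_split_coordinates(pair$value_lat, pair$value_lon,
                                    config$placeholder_tokens)
      okv <- !is.na(ps$latitude)
      split_canon <- tibble::tibble(
        sample_accession = pair$sample_accession[okv],
        key = paste(pair$key_lat[okv], pair$key_lon[okv], sep = "+"),
        ord = pmin(pair$ord_lat[okv], pair$ord_lon[okv]),
        value = ps$raw_text[okv],
        latitude = ps$latitude[okv], longitude = ps$longitude[okv],
        dialect = ps$dialect[okv], zero_zero = ps$zero_zero[okv])
    }
  }
  coord_all <- dplyr::bind_rows(coord_canon, split_canon)
  if (nrow(coord_all)) {
    coord_all <- dplyr::distinct(coord_all, .data$sample_accession,
                                 .keep_all = TRUE)
  }

  # canonical collection-date keys
  date_rows <- attrs[attrs$key %in% config$date_keys, , drop = FALSE]
  date_extra <- empty_recoveries()
  if (nrow(date_rows)) {
    pd <- parse_collection_date(date_rows$value, config$placeholder_tokens)
    dr <- dplyr::bind_cols(
      date_rows[, c("sample_accession", "key", "ord", "value")],
      pd[, c("year", "precision", "range_end_year")])
    ok <- dr[!is.na(dr$year), , drop = FALSE] |>
      dplyr::arrange(.data$sample_accession, .data$ord) |>
      dplyr::group_by(.data$sample_accession) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
    date_canon <- ok[ok$rank == 1, , drop = FALSE]
    extra <- ok[ok$rank > 1, , drop = FALSE]
    if (nrow(extra)) {
      extra$kind <- "temporal"
      extra$latitude <- NA_real_
      extra$longitude <- NA_real_
      extra$dialect <- NA_character_
      extra$zero_zero <- FALSE
      date_extra <- extra[, recovery_columns]
    }
  } else {
    date_canon <- NULL
  }

  # misfiled scan + promotion of the first recovery of each kind into
  # still-empty canonical slots
  recoveries <- empty_recoveries()
  promoted_coord <- NULL
  promoted_date <- NULL
  if (config$scan_misfiled) {
    recoveries <- scan_misfiled_table(attrs, config)
    if (nrow(recoveries)) {
      first_rec <- recoveries |>
        dplyr::arrange(.data$sample_accession, .data$ord) |>
        dplyr::group_by(.data$sample_accession, .data$kind) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
      cr <- first_rec[first_rec$kind == "coordinate", , drop = FALSE]
      if (!is.null(coord_all) && nrow(coord_all)) {
        cr <- cr[!cr$sample_accession %in% coord_all$sample_accession, ,
                 drop = FALSE]
      }
      promoted_coord <- cr
      dr2 <- first_rec[first_rec$kind == "temporal", , drop = FALSE]
      if (!is.null(date_canon) && nrow(date_canon)) {
        dr2 <- dr2[!dr2$sample_accession %in% date_canon$sample_accession, ,
                   drop = FALSE]
      }
      promoted_date <- dr2
    }
  }
  recoveries <- dplyr::bind_rows(recoveries, coord_extra, date_extra) |>
    dplyr::arrange(.data$sample_accession, .data$ord)

  coord_final <- dplyr::bind_rows(
    if (!is.null(coord_all) && nrow(coord_all))
      dplyr::mutate(coord_all, coord_origin = "archive"),
    if (!is.null(promoted_coord) && nrow(promoted_coord))
      dplyr::mutate(promoted_coord, coord_origin = "misfiled"))
  date_final <- dplyr::bind_rows(
    if (!is.null(date_canon) && nrow(date_canon))
      dplyr::mutate(date_canon, year_origin = "archive"),
    if (!is.null(promoted_date) && nrow(promoted_date))
      dplyr::mutate(promoted_date, year_origin = "misfiled"))

  out <- base
  if (!is.null(coord_final) && nrow(coord_final)) {
    out <- dplyr::left_join(out, coord_final |>
      dplyr::transmute(.data$sample_accession, .data$latitude,
                       .data$longitude, coord_dialect = .data$dialect,
                       coord_source_key = .data$key, coord_raw = .data$value,
                       .data$zero_zero, .data$coord_origin),
      by = "sample_accession")
  } else {
    out$latitude <- NA_real_; out$longitude <- NA_real_
    out$coord_dialect <- NA_character_; out$coord_source_key <- NA_character_
    out$coord_raw <- NA_character_; out$zero_zero <- NA
    out$coord_origin <- NA_character_
  }
  if (!is.null(date_final) && nrow(date_final)) {
    out <- dplyr::left_join(out, date_final |>
      dplyr::transmute(.data$sample_accession, .data$year,
                       year_precision = .data$precision,
                       .data$range_end_year,
                       year_source_key = .data$key, year_raw = .data$value,
                       .data$year_origin),
      by = "sample_accession")
  } else {
    out$year <- NA_integer_; out$year_precision <- NA_character_
    out$range_end_year <- NA_integer_; out$year_source_key <- NA_character_
    out$year_raw <- NA_character_; out$year_origin <- NA_character_
  }
  out$zero_zero[is.na(out$zero_zero)] <- FALSE

  # location tier from geographic-name fields + coordinate presence
  loc_rows <- attrs[attrs$key %in% config$loc_keys, , drop = FALSE]
  if (nrow(loc_rows)) {
    pl <- parse_location_value(loc_rows$value, config$gazetteer,
                               config$placeholder_tokens)
    lr <- dplyr::bind_cols(loc_rows[, c("sample_accession", "key", "ord")], pl)
    lr <- dplyr::arrange(lr, .data$sample_accession, .data$ord)
    country_tab <- lr[!is.na(lr$country), ] |>
      dplyr::distinct(.data$sample_accession, .keep_all = TRUE) |>
      dplyr::select("sample_accession", "country")
    place_tab <- lr[!is.na(lr$place), ] |>
      dplyr::distinct(.data$sample_accession, .keep_all = TRUE) |>
      dplyr::select("sample_accession", "place")
    src_tab <- lr[!is.na(lr$country) | !is.na(lr$place), ] |>
      dplyr::distinct(.data$sample_accession, .keep_all = TRUE) |>
      dplyr::select("sample_accession", loc_source_key = "key")
    out <- out |>
      dplyr::left_join(country_tab, by = "sample_accession") |>
      dplyr::left_join(place_tab, by = "sample_accession") |>
      dplyr::left_join(src_tab, by = "sample_accession")
  } else {
    out$country <- NA_character_
    out$place <- NA_character_
    out$loc_source_key <- NA_character_
  }
  out$tier <- ifelse(!is.na(out$latitude), "coordinates",
               ifelse(!is.na(out$place), "place_name",
                ifelse(!is.na(out$country), "country", "none")))

  n_mis <- recoveries |> dplyr::count(.data$sample_accession, name = "n_misfiled")
  out <- dplyr::left_join(out, n_mis, by = "sample_accession")
  out$n_misfiled[is.na(out$n_misfiled)] <- 0L
  list(parsed = out, recoveries = recoveries)
}

#' Parse one sample's attributes into normalized metadata
#'
#' Canonical fields are tried first (combined `lat_lon`, then split
#' latitude/longitude fields, then `collection_date`, then geographic
#' names); if a canonical slot stays empty and misfiled scanning is
#' enabled, the first misfiled recovery of the matching kind (in attribute
#' order -- the only defensible prior) is promoted into the slot and
#' flagged with origin `"misfiled"`.
#'
#' @param attributes a sample's attribute tibble (columns `key`, `value`,
#'   `ord`).
#' @param config a [parser_config()].
#' @return list of class `parsed_metadata`: `coordinate` (one-row tibble or
#'   `NULL`), `temporal` (one-row tibble or `NULL`), `location` (list with
#'   `tier`, `country`, `place`, `source_key`), `misfiled_recoveries`
#'   (tibble).
#' @examples
#' attrs <- tibble::tibble(
#'   key = c("lat_lon", "collection_date"),
#'   value = c("36.21 N 121.77 W", "2008-07-15"), ord = 1:2)
#' parse_sample(attrs)
#' @export
parse_sample <- function(attributes, config = parser_config()) {
  attrs <- tibble::as_tibble(attributes)
  if (!"sample_accession" %in% names(attrs)) attrs$sample_accession <- "sample"
  if (!"ord" %in% names(attrs)) attrs$ord <- seq_len(nrow(attrs))
  ids <- unique(attrs$sample_accession)
  if (!length(ids)) ids <- "sample"
  res <- parse_attr_table(attrs, ids, config)
  row <- res$parsed[1, ]
  coordinate <- NULL
  if (!is.na(row$latitude)) {
    coordinate <- tibble::tibble(
      latitude = row$latitude, longitude = row$longitude,
      dialect = row$coord_dialect, source_key = row$coord_source_key,
      raw_text = row$coord_raw, zero_zero = row$zero_zero,
      origin = row$coord_origin)
  }
  temporal <- NULL
  if (!is.na(row$year)) {
    temporal <- tibble::tibble(
      collection_year = row$year, precision = row$year_precision,
      range_end_year = row$range_end_year, source_key = row$year_source_key,
      raw_text = row$year_raw, origin = row$year_origin)
  }
  structure(list(
    coordinate = coordinate, temporal = temporal,
    location = list(tier = row$tier, country = row$country,
                    place = row$place, source_key = row$loc_source_key),
    misfiled_recoveries = res$recoveries), class = "parsed_metadata")
}

#' Parse every sample in a corpus
#'
#' Runs the full parsing stage over a corpus and attaches the results:
#' `corpus$parsed` gains one row per sample (coordinate, year, location
#' tier, promotion flags), `corpus$recoveries` holds all misfiled
#' recoveries.
#'
#' @param corpus an `insdc_corpus`.
#' @param config a [parser_config()].
#' @return the corpus with `parsed` and `recoveries` components.
#' @export
parse_corpus <- function(corpus, config = parser_config()) {
  res <- parse_attr_table(corpus$attributes, corpus$samples$sample_accession,
                          config)
  corpus$parsed <- res$parsed
  corpus$recoveries <- res$recoveries
  corpus$parser_config <- config
  corpus
}
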