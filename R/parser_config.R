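#' Parser configuration
#'
#' Bundles the knobs that control metadata parsing: which harmonized keys are
#' canonical for each metadata slot, which tokens count as placeholders, the
#' country gazetteer, whether values misfiled under non-canonical keys are
#' scanned and promoted, and whether a (0, 0) coordinate counts as real.
#'
#' The canonical key defaults mirror the BioSample attribute vocabulary:
#' `lat_lon` for combined coordinates, `latitude`/`longitude` (and the
#' `geographic_location_(latitude)` long forms) for split fields,
#' `collection_date` for sampling dates, and `geo_loc_name` (plus
#' `geographic_location_(country_and/or_sea)`) for geographic names in the
#' `"country: region: locality"` convention. They are configuration, not an
#' assertion about any particular archive snapshot.
#'
#' @param coord_keys harmonized keys holding a combined lat/lon value.
#' @param lat_keys,lon_keys harmonized keys holding split coordinate fields.
#' @param date_keys harmonized keys holding collection dates.
#' @param loc_keys harmonized keys holding geographic names.
#' @param placeholder_tokens lower-case tokens meaning "no value".
#' @param gazetteer tibble with columns `country` and `synonyms`
#'   (pipe-separated); default ships with the package.
#' @param scan_misfiled if `TRUE` (default), values under non-canonical keys
#'   are scanned for parseable coordinates/dates and promoted into empty
#'   canonical slots.
#' @param count_zero_zero if `FALSE` (default), a coordinate of exactly
#'   (0, 0) is parsed and flagged but does not count as "has coordinates"
#'   in audits -- (0, 0) is a common submission placeholder.
#' @return a list of class `parser_config`.
#' @export
parser_config <- function(coord_keys = c("lat_lon"),
                          lat_keys = c("latitude",
                                       "geographic_location_(latitude)"),
                          lon_keys = c("longitude",
                                       "geographic_location_(longitude)"),
                          date_keys = c("collection_date"),
                          loc_keys = c("geo_loc_name",
                                       "geographic_location_(country_and/or_sea)"),
                          placeholder_tokens = default_placeholder_tokens(),
                          gazetteer = default_gazetteer(),
                          scan_misfiled = TRUE,
                          count_zero_zero = FALSE) {
  structure(list(coord_keys = coord_keys, lat_keys = lat_keys,
                 lon_keys = lon_keys, date_keys = date_keys,
                 loc_keys = loc_keys,
                 placeholder_tokens = tolower(placeholder_tokens),
                 gazetteer = tibble::as_tibble(gazetteer),
                 scan_misfiled = isTRUE(scan_misfiled),
                 count_zero_zero = isTRUE(count_zero_zero)),
            class = "parser_config")
}

canonical_keys <- function(config) {
  unique(c(config$coord_keys, config$lat_keys, config$lon_keys,
           config$date_keys, config$loc_keys))
}

#' Packaged country-name gazetteer
#'
#' A hand-maintained list of country names with common synonyms
#' (`"UK" -> "United Kingdom"`, `"Brasil" -> "Brazil"`, ...), used to decide
#' whether a geographic-name token is country-level. Editable: pass your own
#' table to [parser_config()].
#'
#' @param path path to a TSV with columns `country` and `synonyms`
#'   (pipe-separated, may be empty).
#' @return tibble with columns `country`, `synonyms`.
#' @export
default_gazetteer <- function(path = system.file("extdata", "countries.tsv",
                                                 package = "insdcmeta")) {
  readr::read_tsv(path, col_types = "cc", na = character(), progress = FALSE)
}

# lookup table: lower-cased name/synonym -> canonical country name
gazetteer_lookup <- function(gazetteer) {
  syn <- strsplit(ifelse(is.na(gazetteer$synonyms), "", gazetteer$synonyms),
                  "|", fixed = TRUE)
  n_syn <- lengths(syn)
  tibble::tibble(
    token = tolower(c(gazetteer$country, unlist(syn))),
    country = c(gazetteer$country, rep(gazetteer$country, n_syn)))
}

#' Match tokens against the country gazetteer
#'
#' @param x character vector of candidate tokens.
#' @param gazetteer gazetteer tibble (see [default_gazetteer()]).
#' @return character vector: the canonical country name where `x` matches a
#'   country name or synonym (case-insensitive, trimmed), `NA` otherwise.
#' @export
match_country <- function(x, gazetteer = default_gazetteer()) {
  lut <- gazetteer_lookup(gazetteer)
  key <- tolower(trimws(as.character(x)))
  lut$country[match(key, lut$token)]
}
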