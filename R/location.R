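#' Parse a geographic-name value into country and place tokens
#'
#' Geographic-name fields follow (loosely) the `"country: region: locality"`
#' convention. A value is split on `:`/`,`/`;`, tokens are trimmed, and each
#' token is matched against the country gazetteer. The country is the first
#' gazetteer match (reported under its canonical name); the place is the
#' *last* non-country, non-placeholder token -- by convention the finest
#' locality (`"USA: Wisconsin, Lake Mendota"` gives country `"USA"`, place
#' `"Lake Mendota"`).
#'
#' @param values character vector of raw geographic-name values.
#' @param gazetteer gazetteer tibble (see [default_gazetteer()]).
#' @param placeholder_tokens lower-case tokens treated as absent.
#' @return tibble with one row per input: `raw_text`, `country`, `place`.
#' @export
parse_location_value <- function(values, gazetteer = default_gazetteer(),
                                 placeholder_tokens = default_placeholder_tokens()) {
  x <- trimws(as.character(values))
  n <- length(x)
  out <- tibble::tibble(raw_text = x,
                        country = rep(NA_character_, n),
                        place = rep(NA_character_, n))
  if (n == 0) return(out)
  lut <- gazetteer_lookup(gazetteer)
  todo <- which(!is_placeholder(x, placeholder_tokens))
  toks <- strsplit(x[todo], "[:,;]")
  for (i in seq_along(todo)) {
    tk <- trimws(toks[[i]])
    tk <- tk[nzchar(tk) & !is_placeholder(tk, placeholder_tokens)]
    if (!length(tk)) next
    hit <- lut$country[match(tolower(tk), lut$token)]
    if (any(!is.na(hit))) out$country[todo[i]] <- hit[which(!is.na(hit))[1]]
    non_country <- tk[is.na(hit)]
    if (length(non_country)) {
      out$place[todo[i]] <- non_country[length(non_country)]
    }
  }
  out
}

#' Assign the location tier of one sample
#'
#' Location evidence is tiered: `coordinates` beat a `place_name`, which
#' beats a bare `country`, which beats `none`. The tier is the best evidence
#' available: `coordinates` whenever a parsed coordinate exists (regardless
#' of name fields), else `place_name` if any geographic-name attribute
#' yields a locality finer than a country, else `country`, else `none`.
#' The country is populated whenever determinable even when the tier is
#' finer, so country-level tallies include samples known to finer precision.
#'
#' @param attributes a sample's attribute tibble (columns `key`, `value`,
#'   `ord`; see [sample_attributes()]).
#' @param has_coordinate logical: does the sample have a parsed coordinate?
#' @param config a [parser_config()].
#' @return list with `tier`, `country`, `place`, `source_key`.
#' @export
extract_location <- function(attributes, has_coordinate = FALSE,
                             config = parser_config()) {
  loc <- attributes[attributes$key %in% config$loc_keys, , drop = FALSE]
  loc <- loc[order(loc$ord), , drop = FALSE]
  country <- NA_character_; place <- NA_character_; src <- NA_character_
  if (nrow(loc)) {
    parsed <- parse_location_value(loc$value, config$gazetteer,
                                   config$placeholder_tokens)
    ci <- which(!is.na(parsed$country))
    pi <- which(!is.na(parsed$place))
    if (length(ci)) country <- parsed$country[ci[1]]
    if (length(pi)) place <- parsed$place[pi[1]]
    first_evid <- c(ci, pi)
    if (length(first_evid)) src <- loc$key[min(first_evid)]
  }
  tier <- if (isTRUE(has_coordinate)) "coordinates"
  else if (!is.na(place)) "place_name"
  else if (!is.na(country)) "country"
  else "none"
  list(tier = tier, country = country, place = place, source_key = src)
}
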