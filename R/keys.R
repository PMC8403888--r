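#' Harmonize an attribute key
#'
#' Archive attribute keys are inconsistently cased and delimited
#' (`"Lat Lon"`, `"lat-lon"`, `"lat_lon"` all occur). Keys are harmonized by
#' lower-casing, trimming, and collapsing runs of spaces/hyphens to a single
#' underscore; the original spelling is kept alongside wherever attributes are
#' stored, so reports can echo what the submitter wrote.
#'
#' @param key character vector of raw attribute keys.
#' @return character vector of harmonized keys.
#' @examples
#' harmonize_key(c("Lat Lon", "lat-lon", "  Collection Date "))
#' @export
harmonize_key <- function(key) {
  k <- tolower(trimws(as.character(key)))
  gsub("[ -]+", "_", k)
}

#' Placeholder tokens that mean "no value"
#'
#' Submitters routinely fill required attribute fields with tokens such as
#' `"missing"` or `"not collected"`. All parsers treat these (case-insensitive,
#' after trimming) as absent values with rejection category `"placeholder"`.
#'
#' @return character vector of placeholder tokens (lower case).
#' @export
default_placeholder_tokens <- function() {
  c("missing", "na", "n/a", "n.a.", "none", "null", "not applicable",
    "not collected", "not provided", "not available", "unknown",
    "unspecified", "not determined", "nd", "-", "--")
}

is_placeholder <- function(x, tokens = default_placeholder_tokens()) {
  v <- tolower(trimws(as.character(x)))
  is.na(x) | v == "" | v %in% tokens
}
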