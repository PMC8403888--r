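# numeric fragment of a coordinate: up to 3 integer digits, optional decimals
.coord_num <- "[0-9]{1,3}(?:\\.[0-9]+)?"
# degree / minute / second symbols, incl. unicode prime variants
.deg_sym <- "[\u00b0\u00ba]"
.min_sym <- "['\u2032]"
.sec_sym <- "[\"\u2033]"

#' Parse combined latitude/longitude strings
#'
#' Recognizes, in priority order, the three combined-value dialects found in
#' archive `lat_lon` fields:
#'
#' 1. *hemisphere letters* -- `"36.21 N 121.77 W"` (the letter may precede or
#'    follow the number; comma or whitespace separated); the letter forces
#'    the sign.
#' 2. *signed decimal* -- `"-36.5, 174.7"`, latitude first (the dominant
#'    archive convention; order is unrecoverable without letters).
#' 3. *degrees-minutes-seconds* -- `"36°12'36\" S 121°46'48\" E"`,
#'    seconds optional and possibly fractional.
#'
#' Placeholder tokens (`"missing"`, `"not collected"`, ...) yield an absent
#' result with reason `"placeholder"`; values outside \eqn{[-90, 90] \times
#' [-180, 180]} yield reason `"out_of_range"`; anything else unrecognized
#' yields `"unparseable"`. No input raises an error. Parsed values are
#' rounded to 6 decimal places (WGS84 decimal degrees are assumed; the audit
#' needs presence and validity, not geodesy).
#'
#' @param raw character vector of raw field values.
#' @param placeholder_tokens lower-case tokens treated as absent.
#' @return tibble with one row per input: `raw_text`, `latitude`,
#'   `longitude`, `dialect`, `zero_zero` (`TRUE` iff both are exactly 0 --
#'   a common placeholder location, flagged so audits can discount it), and
#'   `reason` (`NA` on success, else one of `"placeholder"`,
#'   `"unparseable"`, `"out_of_range"`).
#' @examples
#' parse_lat_lon(c("36.21 N 121.77 W", "-36.5, 174.7", "not collected"))
#' @export
parse_lat_lon <- function(raw, placeholder_tokens = default_placeholder_tokens()) {
  x <- trimws(as.character(raw))
  n <- length(x)
  out <- tibble::tibble(raw_text = x,
                        latitude = rep(NA_real_, n),
                        longitude = rep(NA_real_, n),
                        dialect = rep(NA_character_, n),
                        zero_zero = rep(FALSE, n),
                        reason = rep(NA_character_, n))
  if (n == 0) return(out)
  ph <- is_placeholder(x, placeholder_tokens)
  out$reason[ph] <- "placeholder"
  todo <- which(!ph)

  # dialect 1: hemisphere letters, letter after ("36.2 N 121.7 W") or
  # before ("N 36.2, W 121.7") its number
  if (length(todo)) {
    pat_after <- paste0("^(", .coord_num, ")\\s*([NSns])[\\s,;]+(",
                        .coord_num, ")\\s*([EWew])$")
    pat_before <- paste0("^([NSns])\\s*(", .coord_num, ")[\\s,;]+([EWew])\\s*(",
                         .coord_num, ")$")
    for (pat in c(pat_after, pat_before)) {
      if (!length(todo)) break
      m <- regmatches(x[todo], regexec(pat, x[todo], perl = TRUE))
      hit <- lengths(m) == 5
      if (any(hit)) {
        g <- do.call(rbind, m[hit])
        if (pat == pat_before) g <- g[, c(1, 3, 2, 5, 4), drop = FALSE]
        lat <- as.numeric(g[, 2]) * ifelse(toupper(g[, 3]) == "S", -1, 1)
        lon <- as.numeric(g[, 4]) * ifelse(toupper(g[, 5]) == "W", -1, 1)
        out <- fill_coord(out, todo[hit], lat, lon, "hemisphere_letters")
        todo <- todo[!hit]
      }
    }
  }

  # dialect 2: signed decimal pair, latitude first
  if (length(todo)) {
    pat <- paste0("^([+-]?", .coord_num, ")[\\s,;]+([+-]?", .coord_num, ")$")
    m <- regmatches(x[todo], regexec(pat, x[todo], perl = TRUE))
    hit <- lengths(m) == 3
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      out <- fill_coord(out, todo[hit], as.numeric(g[, 2]),
                        as.numeric(g[, 3]), "signed_decimal")
      todo <- todo[!hit]
    }
  }

  # dialect 3: DMS pairs
  if (length(todo)) {
    part <- paste0("([0-9]{1,3})\\s*", .deg_sym, "\\s*([0-9]{1,2})\\s*",
                   .min_sym, "\\s*(?:([0-9]{1,2}(?:\\.[0-9]+)?)\\s*",
                   .sec_sym, ")?\\s*")
    pat <- paste0("^", part, "([NSns])[\\s,;]+", part, "([EWew])$")
    m <- regmatches(x[todo], regexec(pat, x[todo], perl = TRUE))
    hit <- lengths(m) == 9
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      lat <- dms_to_decimal(g[, 2], g[, 3], g[, 4]) *
        ifelse(toupper(g[, 5]) == "S", -1, 1)
      lon <- dms_to_decimal(g[, 6], g[, 7], g[, 8]) *
        ifelse(toupper(g[, 9]) == "W", -1, 1)
      out <- fill_coord(out, todo[hit], lat, lon, "dms")
      todo <- todo[!hit]
    }
  }

  out$reason[todo] <- "unparseable"
  out
}

dms_to_decimal <- function(deg, min, sec) {
  sec_n <- suppressWarnings(as.numeric(sec))
  sec_n[is.na(sec_n)] <- 0
  as.numeric(deg) + as.numeric(min) / 60 + sec_n / 3600
}

# write lat/lon into rows idx, demoting out-of-range hits to a reason
fill_coord <- function(out, idx, lat, lon, dialect) {
  ok <- abs(lat) <= 90 & abs(lon) <= 180
  good <- idx[ok]
  out$latitude[good] <- round(lat[ok], 6)
  out$longitude[good] <- round(lon[ok], 6)
  out$dialect[good] <- dialect
  out$zero_zero[good] <- out$latitude[good] == 0 & out$longitude[good] == 0
  out$reason[idx[!ok]] <- "out_of_range"
  out
}

#' Parse split latitude and longitude fields
#'
#' Archives also carry coordinates as separate `latitude` and `longitude`
#' attributes. Each field is parsed as a single signed or
#' hemisphere-suffixed (or -prefixed) decimal value; both must parse and lie
#' in range for a coordinate to result. The dialect is recorded as
#' `"split_fields"`.
#'
#' @param lat_raw,lon_raw character vectors (recycled to equal length) of
#'   raw field values.
#' @param placeholder_tokens lower-case tokens treated as absent.
#' @return tibble as in [parse_lat_lon()].
#' @examples
#' parse_split_coordinates(c("-36.5", "36.5 S"), c("174.7", "174.7 E"))
#' @export
parse_split_coordinates <- function(lat_raw, lon_raw,
                                    placeholder_tokens = default_placeholder_tokens()) {
  n <- max(length(lat_raw), length(lon_raw))
  lat_raw <- rep_len(as.character(lat_raw), n)
  lon_raw <- rep_len(as.character(lon_raw), n)
  lat <- parse_single_coordinate(lat_raw, c("N", "S"), 90, placeholder_tokens)
  lon <- parse_single_coordinate(lon_raw, c("E", "W"), 180, placeholder_tokens)
  out <- tibble::tibble(
    raw_text = paste(trimws(lat_raw), trimws(lon_raw), sep = " | "),
    latitude = lat$value, longitude = lon$value,
    dialect = rep(NA_character_, n), zero_zero = rep(FALSE, n),
    reason = dplyr::coalesce(lat$reason, lon$reason))
  ok <- !is.na(out$latitude) & !is.na(out$longitude)
  out$latitude[!ok] <- NA_real_
  out$longitude[!ok] <- NA_real_
  out$dialect[ok] <- "split_fields"
  out$zero_zero[ok] <- out$latitude[ok] == 0 & out$longitude[ok] == 0
  out
}

# one axis of a split coordinate: "-36.5", "36.5 S", "S 36.5"
parse_single_coordinate <- function(raw, letters, bound, placeholder_tokens) {
  x <- trimws(as.character(raw))
  n <- length(x)
  value <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  ph <- is_placeholder(x, placeholder_tokens)
  reason[ph] <- "placeholder"
  lset <- paste0(c(letters, tolower(letters)), collapse = "")
  pat <- paste0("^(?:([", lset, "])\\s*)?([+-]?", .coord_num,
                ")(?:\\s*([", lset, "]))?$")
  todo <- which(!ph)
  m <- regmatches(x[todo], regexec(pat, x[todo], perl = TRUE))
  hit <- lengths(m) == 4
  if (any(hit)) {
    g <- do.call(rbind, m[hit])
    v <- as.numeric(g[, 3])
    letter <- toupper(ifelse(nzchar(g[, 2]), g[, 2], g[, 4]))
    neg <- letter %in% c("S", "W")
    v[neg] <- -abs(v[neg])
    idx <- todo[hit]
    in_range <- abs(v) <= bound
    value[idx[in_range]] <- round(v[in_range], 6)
    reason[idx[!in_range]] <- "out_of_range"
  }
  reason[todo[!hit]] <- "unparseable"
  list(value = value, reason = reason)
}
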