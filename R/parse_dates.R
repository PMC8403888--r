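#' Parse collection-date strings to a collection year
#'
#' The audit needs a collection *year*; full dates are welcome but only the
#' year (and its precision) is retained. Recognized forms, in priority
#' order:
#'
#' * ISO 8601 `YYYY-MM-DD` (precision `"day"`), `YYYY-MM` (`"month"`),
#'   bare `YYYY` (`"year"`);
#' * year ranges `YYYY/YYYY` or `YYYY-YYYY` (precision `"range"`; the
#'   *earliest* year is used as the collection year -- a conservative single
#'   timestamp -- with the latest in `range_end_year` so range-coded records
#'   stay identifiable for sensitivity analyses);
#' * `DD-Mon-YYYY` (`"day"`) and `Mon-YYYY` (`"month"`) with English month
#'   names or abbreviations;
#' * a bare 4-digit year embedded anywhere in free text (`"sampled in 2012
#'   from reef"`; precision `"year"`).
#'
#' Placeholder tokens yield reason `"placeholder"`. Years outside the
#' plausibility window `[1800, current year]` -- wide enough for historical
#' museum material, narrow enough to exclude obvious typos -- yield
#' `"out_of_range"`; all other failures `"unparseable"`. No input raises.
#'
#' @param raw character vector of raw field values.
#' @param placeholder_tokens lower-case tokens treated as absent.
#' @param max_year upper end of the plausibility window (defaults to the
#'   current year).
#' @return tibble with one row per input: `raw_text`, `year`, `precision`
#'   (`"day"`, `"month"`, `"year"`, `"range"`), `range_end_year`, `reason`.
#' @examples
#' parse_collection_date(c("2008-07-15", "Jul-2009", "2008/2010", "unknown"))
#' @export
parse_collection_date <- function(raw,
                                  placeholder_tokens = default_placeholder_tokens(),
                                  max_year = current_year()) {
  x <- trimws(as.character(raw))
  n <- length(x)
  out <- tibble::tibble(raw_text = x,
                        year = rep(NA_integer_, n),
                        precision = rep(NA_character_, n),
                        range_end_year = rep(NA_integer_, n),
                        reason = rep(NA_character_, n))
  if (n == 0) return(out)
  ph <- is_placeholder(x, placeholder_tokens)
  out$reason[ph] <- "placeholder"
  todo <- which(!ph)

  take <- function(idx, year, precision, range_end = NA_integer_) {
    year <- as.integer(year)
    range_end <- as.integer(range_end)
    ok <- year >= 1800L & year <= max_year &
      (is.na(range_end) | (range_end >= year & range_end <= max_year))
    out$year[idx[ok]] <<- year[ok]
    out$precision[idx[ok]] <<- precision
    out$range_end_year[idx[ok]] <<- if (length(range_end) == 1)
      rep(range_end, sum(ok)) else range_end[ok]
    out$reason[idx[!ok]] <<- "out_of_range"
    idx[is.na(out$year[idx]) & is.na(out$reason[idx])]
  }

  # ISO full date
  if (length(todo)) {
    m <- regmatches(x[todo],
                    regexec("^([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})$", x[todo]))
    hit <- lengths(m) == 4
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      valid <- as.integer(g[, 3]) >= 1 & as.integer(g[, 3]) <= 12 &
        as.integer(g[, 4]) >= 1 & as.integer(g[, 4]) <= 31
      idx <- todo[hit][valid]
      if (length(idx)) take(idx, g[valid, 2], "day")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # year range: 2008/2010 or 2008-2010 (earliest year rule)
  if (length(todo)) {
    m <- regmatches(x[todo],
                    regexec("^([0-9]{4})\\s*[/-]\\s*([0-9]{4})$", x[todo]))
    hit <- lengths(m) == 3
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      y1 <- pmin(as.integer(g[, 2]), as.integer(g[, 3]))
      y2 <- pmax(as.integer(g[, 2]), as.integer(g[, 3]))
      idx <- todo[hit]
      take(idx, y1, "range", y2)
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # ISO year-month
  if (length(todo)) {
    m <- regmatches(x[todo], regexec("^([0-9]{4})-([0-9]{1,2})$", x[todo]))
    hit <- lengths(m) == 3
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      valid <- as.integer(g[, 3]) >= 1 & as.integer(g[, 3]) <= 12
      idx <- todo[hit][valid]
      if (length(idx)) take(idx, g[valid, 2], "month")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # DD-Mon-YYYY
  if (length(todo)) {
    m <- regmatches(x[todo],
      regexec("^([0-9]{1,2})[- ]([A-Za-z]{3,9})[- ]([0-9]{4})$", x[todo]))
    hit <- lengths(m) == 4
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      valid <- month_number(g[, 3]) > 0 &
        as.integer(g[, 2]) >= 1 & as.integer(g[, 2]) <= 31
      valid[is.na(valid)] <- FALSE
      idx <- todo[hit][valid]
      if (length(idx)) take(idx, g[valid, 4], "day")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # Mon-YYYY
  if (length(todo)) {
    m <- regmatches(x[todo],
                    regexec("^([A-Za-z]{3,9})[- ]([0-9]{4})$", x[todo]))
    hit <- lengths(m) == 3
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      valid <- month_number(g[, 2]) > 0
      valid[is.na(valid)] <- FALSE
      idx <- todo[hit][valid]
      if (length(idx)) take(idx, g[valid, 3], "month")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # bare integer: a year candidate, window-checked ("0" is out of window)
  if (length(todo)) {
    hit <- grepl("^[0-9]{1,4}$", x[todo])
    if (any(hit)) {
      idx <- todo[hit]
      take(idx, x[idx], "year")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  # 4-digit year embedded in free text
  if (length(todo)) {
    m <- regmatches(x[todo],
                    regexec("(?<![0-9])([0-9]{4})(?![0-9])", x[todo], perl = TRUE))
    hit <- lengths(m) == 2
    if (any(hit)) {
      g <- do.call(rbind, m[hit])
      idx <- todo[hit]
      take(idx, g[, 2], "year")
      todo <- setdiff(todo, idx)
      todo <- todo[is.na(out$reason[todo])]
    }
  }

  out$reason[todo] <- "unparseable"
  out
}

month_number <- function(name) {
  match(tolower(substr(name, 1, 3)), tolower(month.abb), nomatch = 0L)
}
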