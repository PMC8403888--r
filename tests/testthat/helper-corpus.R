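# attribute tibble from key = value pairs, in call order
make_attrs <- function(...) {
  kv <- list(...)
  tibble::tibble(key = harmonize_key(names(kv)),
                 key_raw = names(kv),
                 value = unname(unlist(kv)),
                 ord = seq_along(kv))
}

# hand-built corpus: `samples` is a list of lists with fields
# acc, ds, taxon, year, attrs (a make_attrs() tibble)
make_corpus <- function(samples) {
  smp <- dplyr::bind_rows(lapply(samples, function(s) tibble::tibble(
    sample_accession = s$acc,
    taxon_name = s$taxon %||% "Danio rerio",
    taxon_id = NA_integer_,
    deposition_year = s$year %||% NA_integer_)))
  attrs <- dplyr::bind_rows(lapply(samples, function(s) {
    a <- s$attrs %||% make_attrs(library_strategy = "WGS")
    a$sample_accession <- s$acc
    a
  }))
  mem <- dplyr::bind_rows(lapply(samples, function(s) tibble::tibble(
    dataset_accession = s$ds %||% "PRJT000001",
    sample_accession = s$acc)))
  new_corpus(smp, attrs, mem, provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ten-sample corpus with a known status layout:
# 3 both, 2 coords_only, 4 year_only, 1 neither
fixture_status_corpus <- function() {
  mk <- function(i, coord, year) {
    a <- list()
    if (!is.na(coord)) a$lat_lon <- coord
    if (!is.na(year)) a$collection_date <- year
    a$library_strategy <- "WGS"
    list(acc = sprintf("SAMT%02d", i), ds = "PRJT000001",
         attrs = do.call(make_attrs, a))
  }
  make_corpus(list(
    mk(1, "10.1 N 20.2 E", "2010"), mk(2, "11.1 N 21.2 E", "2011"),
    mk(3, "12.1 N 22.2 E", "2012"),
    mk(4, "13.1 N 23.2 E", NA), mk(5, "14.1 N 24.2 E", NA),
    mk(6, NA, "2013"), mk(7, NA, "2014"), mk(8, NA, "2015"),
    mk(9, NA, "2016"),
    mk(10, NA, NA)))
}

# a corpus whose datasets have a chosen number of wild/nonwild members
fixture_wildness_corpus <- function(spec) {
  samples <- list()
  i <- 0
  for (ds in names(spec)) {
    n_wild <- spec[[ds]]["wild"]
    n_dom <- spec[[ds]]["dom"]
    for (k in seq_len(n_wild)) {
      i <- i + 1
      samples[[i]] <- list(acc = sprintf("SAMW%04d", i), ds = ds,
                           attrs = make_attrs(library_strategy = "WGS"))
    }
    for (k in seq_len(n_dom)) {
      i <- i + 1
      samples[[i]] <- list(acc = sprintf("SAMW%04d", i), ds = ds,
                           attrs = make_attrs(breed = "breed line 1",
                                              library_strategy = "WGS"))
    }
  }
  make_corpus(samples)
}

make_empty_corpus <- function() {
  new_corpus(
    samples = tibble::tibble(sample_accession = character(),
                             taxon_name = character(), taxon_id = integer(),
                             deposition_year = integer()),
    attributes = tibble::tibble(sample_accession = character(),
                                key = character(), key_raw = character(),
                                value = character(), ord = integer()),
    memberships = tibble::tibble(dataset_accession = character(),
                                 sample_accession = character(),
                                 unlinked = logical()))
}

# deterministic pseudo-random garble strings for totality tests
garble_strings <- function(n, seed = 99) {
  set.seed(seed)
  chars <- c(letters, LETTERS, 0:9, " ", ",", ".", "-", ":", ";", "/", "(",
             ")", "°", "'", "\"", "N", "S", "E", "W")
  vapply(seq_len(n), function(i) {
    paste(sample(chars, sample(1:20, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# independently coded percentile bootstrap sharing the seed stream:
# same single sample.int call, but loop-and-sort arithmetic downstream
oracle_bootstrap <- function(x, n_reps, seed, ci_level) {
  x <- as.numeric(x)
  n <- length(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  idx <- sample.int(n, n * n_reps, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  means <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    take <- idx[((r - 1) * n + 1):(r * n)]
    means[r] <- sum(x[take]) / n
  }
  sorted <- sort(means)
  q7 <- function(p) {
    h <- (n_reps - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  alpha <- (1 - ci_level) / 2
  c(q7(alpha), q7(1 - alpha))
}

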