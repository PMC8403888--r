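#' Configuration for the synthetic corpus generator
#'
#' Describes a generative model of an archive corpus: how many datasets,
#' how large they are, how often spatial and temporal metadata are truly
#' present (with explicit dependence between the two), which text dialects
#' carry them, how often present values are masked by placeholder tokens or
#' misfiled under the wrong key, and how wild/domesticated/captive
#' provenance signals are planted.
#'
#' The coordinate/year joint law is controlled by one excess-probability
#' parameter: `P(both) = p_coords * p_year + p_both_excess` (the remaining
#' cells follow). Real archives show strong positive dependence --
#' submitters who record where usually also record when -- and a single
#' excess parameter reproduces that without a full copula.
#'
#' Wildness and provenance ambiguity are assigned per *dataset*: a
#' submission is a single study, so its samples share provenance, and
#' filter validation operates at dataset level. A nonwild dataset carries
#' detectable keyword signals in its samples unless it is ambiguous (with
#' probability `p_ambiguous_provenance`), in which case the keyword filter
#' will wrongly call it wild -- this is the dial that makes filter
#' precision less than 1.
#'
#' @param n_datasets number of datasets.
#' @param size_mu,size_disp mean and dispersion (`size`) of the
#'   zero-truncated negative binomial dataset-size distribution.
#' @param p_coords,p_year marginal probabilities that a sample truly has
#'   coordinates / a collection year.
#' @param p_both_excess excess of `P(both)` over independence.
#' @param p_place_given_no_coords probability a sample without coordinates
#'   has a place name (samples with a place name also carry a country, per
#'   the `"country: locality"` convention).
#' @param p_country_given_no_place probability a sample with neither
#'   coordinates-tier evidence nor a place has a bare country name.
#' @param dialect_mixture named weights over the four coordinate dialects.
#' @param p_placeholder probability a truly present field is masked by a
#'   placeholder token (metadata destroyed at deposition).
#' @param p_misfiled probability a present, unmasked value lands under a
#'   non-canonical key instead of its canonical one.
#' @param wild_mixture named weights over `wild`, `domesticated`,
#'   `captive` dataset provenance.
#' @param p_ambiguous_provenance probability a nonwild dataset carries no
#'   detectable keyword.
#' @param taxon_group_weights named weights over taxon groups.
#' @param deposition_year_range integer vector `c(first, last)`.
#' @param growth_rate exponential growth rate of depositions per year.
#' @param seed integer seed; the generator derives one substream per
#'   concern (structure, values, masking, provenance) so that toggling one
#'   concern leaves the others' draws unchanged.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_datasets = 100,
                             size_mu = 8, size_disp = 1,
                             p_coords = 0.3, p_year = 0.5,
                             p_both_excess = 0.1,
                             p_place_given_no_coords = 0.4,
                             p_country_given_no_place = 0.5,
                             dialect_mixture = c(hemisphere_letters = 0.4,
                                                 signed_decimal = 0.3,
                                                 dms = 0.15,
                                                 split_fields = 0.15),
                             p_placeholder = 0.1,
                             p_misfiled = 0.05,
                             wild_mixture = c(wild = 0.6,
                                              domesticated = 0.25,
                                              captive = 0.15),
                             p_ambiguous_provenance = 0.3,
                             taxon_group_weights = c(fish = 0.3,
                                                     mammals = 0.2,
                                                     birds = 0.15,
                                                     insects = 0.15,
                                                     plants = 0.15,
                                                     other = 0.05),
                             deposition_year_range = c(2008L, 2020L),
                             growth_rate = 0.3,
                             seed = 1L) {
  probs <- c(p_coords = p_coords, p_year = p_year,
             p_place = p_place_given_no_coords,
             p_country = p_country_given_no_place,
             p_placeholder = p_placeholder, p_misfiled = p_misfiled,
             p_ambiguous = p_ambiguous_provenance)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  for (mx in list(dialect_mixture, wild_mixture, taxon_group_weights)) {
    if (abs(sum(mx) - 1) > 1e-8) stop("mixture weights must sum to 1")
  }
  p_both <- p_coords * p_year + p_both_excess
  if (p_both < 0 || p_both > min(p_coords, p_year) ||
      1 - p_coords - p_year + p_both < 0) {
    stop("infeasible joint law: P(both) = ", round(p_both, 4),
         " must lie in [max(0, p_coords + p_year - 1), min(p_coords, p_year)]")
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 size_mu = size_mu, size_disp = size_disp,
                 p_coords = p_coords, p_year = p_year,
                 p_both_excess = p_both_excess, p_both = p_both,
                 p_place_given_no_coords = p_place_given_no_coords,
                 p_country_given_no_place = p_country_given_no_place,
                 dialect_mixture = dialect_mixture,
                 p_placeholder = p_placeholder, p_misfiled = p_misfiled,
                 wild_mixture = wild_mixture,
                 p_ambiguous_provenance = p_ambiguous_provenance,
                 taxon_group_weights = taxon_group_weights,
                 deposition_year_range = as.integer(deposition_year_range),
                 growth_rate = growth_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Render a coordinate in a named dialect
#'
#' Inverse of the coordinate parsers up to stated tolerance: decimal
#' dialects render with 6 decimals (round trip exact at 1e-6), DMS renders
#' seconds to 0.1" (round trip within 1e-4 degrees).
#'
#' @param latitude,longitude numeric vectors.
#' @param dialect one of `hemisphere_letters`, `signed_decimal`, `dms`,
#'   `split_fields` (recycled).
#' @return tibble with `text` (combined value; `NA` for split_fields) and
#'   `lat_text`/`lon_text` (split fields; `NA` otherwise).
#' @export
render_coordinate <- function(latitude, longitude, dialect) {
  n <- max(length(latitude), length(longitude), length(dialect))
  lat <- rep_len(latitude, n); lon <- rep_len(longitude, n)
  dia <- rep_len(dialect, n)
  bad <- !dia %in% c("hemisphere_letters", "signed_decimal", "dms",
                     "split_fields")
  if (any(bad)) stop("unknown dialect: ", paste(unique(dia[bad]), collapse = ", "))
  ns <- ifelse(lat < 0, "S", "N"); ew <- ifelse(lon < 0, "W", "E")
  text <- rep(NA_character_, n)
  lat_text <- rep(NA_character_, n); lon_text <- rep(NA_character_, n)
  i <- dia == "hemisphere_letters"
  text[i] <- sprintf("%.6f %s %.6f %s", abs(lat[i]), ns[i], abs(lon[i]), ew[i])
  i <- dia == "signed_decimal"
  text[i] <- sprintf("%.6f, %.6f", lat[i], lon[i])
  i <- dia == "dms"
  text[i] <- paste0(to_dms(lat[i]), " ", ns[i], " ", to_dms(lon[i]), " ", ew[i])
  i <- dia == "split_fields"
  lat_text[i] <- sprintf("%.6f", lat[i])
  lon_text[i] <- sprintf("%.6f", lon[i])
  tibble::tibble(text = text, lat_text = lat_text, lon_text = lon_text)
}

to_dms <- function(v) {
  av <- abs(v)
  d <- floor(av)
  rem <- (av - d) * 60
  m <- floor(rem)
  s <- round((rem - m) * 60, 1)
  roll <- s >= 60; s[roll] <- 0; m[roll] <- m[roll] + 1
  roll <- m >= 60; m[roll] <- 0; d[roll] <- d[roll] + 1
  sprintf("%d\u00b0%d'%.1f\"", d, m, s)
}

#' Render a collection year in a supported date format
#'
#' @param year integer years.
#' @param precision `"year"`, `"month"`, `"day"`, or `"range"` (recycled).
#' @param range_end_year end year for ranges.
#' @param month,day components for month/day precision.
#' @param style `"iso"` (default) or `"name"` (`Mon-YYYY` / `DD-Mon-YYYY`).
#' @return character vector.
#' @export
render_collection_date <- function(year, precision, range_end_year = NA,
                                   month = 6L, day = 15L, style = "iso") {
  n <- max(length(year), length(precision))
  year <- rep_len(as.integer(year), n)
  precision <- rep_len(precision, n)
  range_end_year <- rep_len(as.integer(range_end_year), n)
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  style <- rep_len(style, n)
  out <- rep(NA_character_, n)
  i <- precision == "year"
  out[i] <- sprintf("%d", year[i])
  i <- precision == "range"
  out[i] <- sprintf("%d/%d", year[i], range_end_year[i])
  i <- precision == "month" & style == "iso"
  out[i] <- sprintf("%d-%02d", year[i], month[i])
  i <- precision == "month" & style != "iso"
  out[i] <- sprintf("%s-%d", month.abb[month[i]], year[i])
  i <- precision == "day" & style == "iso"
  out[i] <- sprintf("%d-%02d-%02d", year[i], month[i], day[i])
  i <- precision == "day" & style != "iso"
  out[i] <- sprintf("%02d-%s-%d", day[i], month.abb[month[i]], year[i])
  bad <- is.na(out) & !is.na(precision)
  if (any(bad)) stop("unknown precision: ",
                     paste(unique(precision[bad]), collapse = ", "))
  out
}

# taxon pools per group, split into wild-plausible and domesticated
wild_taxon_pool <- function() {
  g <- default_taxon_groups()
  g[!names(g) %in% scope_rules()$domesticated_taxa]
}

synthetic_place_pool <- c(
  "Lake Mendota", "Blue Mountain", "Coral Bay", "Upper Bend", "Dry Creek",
  "North Ridge", "Willow Flats", "Sandy Point", "Deep Cove", "Misty Valley",
  "Stony Brook", "Windy Pass", "Green Gorge", "Silver Falls", "Long Meadow",
  "Twin Lakes")

synthetic_country_pool <- c(
  "USA", "Canada", "Mexico", "Brazil", "Chile", "France", "Germany", "Spain",
  "Norway", "Sweden", "Poland", "Greece", "Russia", "China", "Japan", "India",
  "Thailand", "Indonesia", "Australia", "New Zealand", "South Africa",
  "Kenya", "Madagascar", "Fiji")

synthetic_placeholder_pool <- c("missing", "not collected", "NA", "unknown",
                                "not provided")

#' Generate a synthetic corpus with ground truth
#'
#' Draws a corpus from the generative model in a [synthetic_config()] and
#' returns it together with the per-sample truth needed for recovery tests:
#' the true coordinate/year (if any), the true location tier and wildness,
#' and whether each value was placeholder-masked or misfiled. Fully
#' deterministic given the config seed; one seeded substream per concern
#' (structure, values, masking, provenance) so changing, say, the misfiled
#' rate does not perturb which samples have coordinates.
#'
#' @param config a [synthetic_config()].
#' @return list: `corpus` (an `insdc_corpus`), `truth` (per-sample tibble),
#'   `dataset_truth` (per-dataset tibble with `dataset_accession`,
#'   `is_wild`, `true_wildness`, `ambiguous`), `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nd <- config$n_datasets

  ## substream 1: structure (datasets, sizes, taxa, years, provenance truth)
  str_draw <- with_seed(config$seed, {
    p0 <- pnbinom(0, size = config$size_disp, mu = config$size_mu)
    sizes <- qnbinom(runif(nd, p0, 1), size = config$size_disp,
                     mu = config$size_mu)
    yr <- seq(config$deposition_year_range[1], config$deposition_year_range[2])
    wts <- exp(config$growth_rate * (yr - yr[1]))
    dep_year <- sample(yr, nd, replace = TRUE, prob = wts / sum(wts))
    wildness <- sample(names(config$wild_mixture), nd, replace = TRUE,
                       prob = config$wild_mixture)
    ambiguous <- runif(nd) < config$p_ambiguous_provenance
    group <- sample(names(config$taxon_group_weights), nd, replace = TRUE,
                    prob = config$taxon_group_weights)
    pool <- wild_taxon_pool()
    taxon <- vapply(group, function(g) {
      cand <- names(pool)[pool == g]
      if (!length(cand)) cand <- names(pool)
      cand[sample.int(length(cand), 1)]
    }, character(1), USE.NAMES = FALSE)
    strategy <- sample(c("WGS", "RAD-Seq", "WXS", "GBS"), nd, replace = TRUE,
                       prob = c(0.4, 0.35, 0.1, 0.15))
    list(sizes = pmax(sizes, 1L), dep_year = dep_year, wildness = wildness,
         ambiguous = ambiguous, group = group, taxon = taxon,
         strategy = strategy)
  })
  ns <- sum(str_draw$sizes)
  ds_acc <- sprintf("PRJS%06d", seq_len(nd))
  ds_of_sample <- rep(seq_len(nd), str_draw$sizes)
  smp_acc <- sprintf("SAMS%08d", seq_len(ns))

  ## substream 2: values (presence cells, coordinates, years, names, dialects)
  val <- with_seed(config$seed + 1L, {
    u <- runif(ns)
    p_both <- config$p_both
    p_conly <- config$p_coords - p_both
    p_yonly <- config$p_year - p_both
    cell <- ifelse(u < p_both, "both",
             ifelse(u < p_both + p_conly, "coords_only",
              ifelse(u < p_both + p_conly + p_yonly, "year_only", "neither")))
    lat <- round(runif(ns, -65, 75), 4)
    lon <- round(runif(ns, -179, 179), 4)
    dialect <- sample(names(config$dialect_mixture), ns, replace = TRUE,
                      prob = config$dialect_mixture)
    dep <- str_draw$dep_year[ds_of_sample]
    year <- dep - (sample.int(15L, ns, replace = TRUE) - 1L)
    year <- pmax(year, 1982L)
    precision <- sample(c("day", "month", "year", "range"), ns,
                        replace = TRUE, prob = c(0.45, 0.15, 0.3, 0.1))
    month <- sample.int(12L, ns, replace = TRUE)
    day <- sample.int(28L, ns, replace = TRUE)
    range_span <- sample.int(3L, ns, replace = TRUE)
    date_style <- sample(c("iso", "name"), ns, replace = TRUE,
                         prob = c(0.8, 0.2))
    has_place <- runif(ns) < config$p_place_given_no_coords
    has_country_alone <- runif(ns) < config$p_country_given_no_place
    place <- sample(synthetic_place_pool, ns, replace = TRUE)
    country <- sample(synthetic_country_pool, ns, replace = TRUE)
    list(cell = cell, lat = lat, lon = lon, dialect = dialect, year = year,
         precision = precision, month = month, day = day,
         range_span = range_span, date_style = date_style,
         has_place = has_place, has_country_alone = has_country_alone,
         place = place, country = country)
  })

  ## substream 3: masking (placeholders, misfiling, absent-field tokens)
  mask <- with_seed(config$seed + 2L, {
    list(coord_mask = runif(ns) < config$p_placeholder,
         year_mask = runif(ns) < config$p_placeholder,
         coord_mis = runif(ns) < config$p_misfiled,
         year_mis = runif(ns) < config$p_misfiled,
         coord_absent_tok = runif(ns) < 0.5,
         year_absent_tok = runif(ns) < 0.5,
         tok_coord = sample(synthetic_placeholder_pool, ns, replace = TRUE),
         tok_year = sample(synthetic_placeholder_pool, ns, replace = TRUE))
  })

  ## substream 4: provenance signal choice for nonwild, unambiguous datasets
  prov <- with_seed(config$seed + 3L, {
    list(dom_sig = sample.int(4L, ns, replace = TRUE),
         cap_sig = sample.int(4L, ns, replace = TRUE))
  })

  has_coords <- val$cell %in% c("both", "coords_only")
  has_year <- val$cell %in% c("both", "year_only")
  coord_masked <- has_coords & mask$coord_mask
  year_masked <- has_year & mask$year_mask
  coord_misfiled <- has_coords & !coord_masked & mask$coord_mis
  year_misfiled <- has_year & !year_masked & mask$year_mis

  # location-name truth: placeful samples also carry their country
  place_present <- val$has_place
  country_present <- place_present | val$has_country_alone
  true_tier <- ifelse(has_coords, "coordinates",
                ifelse(place_present, "place_name",
                 ifelse(country_present, "country", "none")))

  wildness_s <- str_draw$wildness[ds_of_sample]
  ambiguous_s <- str_draw$ambiguous[ds_of_sample]

  ## ---- attribute assembly (vectorized; type_ord fixes within-sample order)
  rows <- list()
  add_rows <- function(sel, key, value, type_ord) {
    if (!any(sel)) return(invisible(NULL))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_accession = smp_acc[sel],
      key_raw = if (length(key) == 1) key else key[sel],
      value = if (length(value) == 1) value else value[sel],
      type_ord = type_ord)
    invisible(NULL)
  }

  geo_val <- ifelse(place_present, paste0(val$country, ": ", val$place),
                    val$country)
  add_rows(country_present, "geo_loc_name", geo_val, 1)

  rc <- render_coordinate(val$lat, val$lon, val$dialect)
  canon_coord <- has_coords & !coord_masked & !coord_misfiled
  split_sel <- canon_coord & val$dialect == "split_fields"
  add_rows(canon_coord & !split_sel, "lat_lon", rc$text, 2)
  add_rows(split_sel, "latitude", rc$lat_text, 2)
  add_rows(split_sel, "longitude", rc$lon_text, 3)
  add_rows(coord_masked, "lat_lon", mask$tok_coord, 2)
  add_rows(!has_coords & mask$coord_absent_tok, "lat_lon", mask$tok_coord, 2)
  mis_dialect <- ifelse(val$dialect == "split_fields", "hemisphere_letters",
                        val$dialect)
  rc_mis <- render_coordinate(val$lat, val$lon, mis_dialect)
  add_rows(coord_misfiled, "isolation_source", rc_mis$text, 7)

  date_text <- render_collection_date(val$year, val$precision,
                                      pmin(val$year + val$range_span,
                                           current_year()),
                                      val$month, val$day, val$date_style)
  canon_year <- has_year & !year_masked & !year_misfiled
  add_rows(canon_year, "collection_date", date_text, 4)
  add_rows(year_masked, "collection_date", mask$tok_year, 4)
  add_rows(!has_year & mask$year_absent_tok, "collection_date",
           mask$tok_year, 4)
  add_rows(year_misfiled, "description",
           sprintf("sampled in %d from the field", val$year), 8)

  add_rows(rep(TRUE, ns), "library_strategy",
           str_draw$strategy[ds_of_sample], 5)

  dom_signals_key <- c("breed", "cultivar", "sample_type", "isolation_source")
  dom_signals_val <- c("breed line 3", "cv. Sonora", "farmed stock",
                       "aquaculture facility")
  cap_signals_key <- c("source_material", "sample_type", "isolation_source",
                       "note")
  cap_signals_val <- c("captive bred individual", "zoo collection",
                       "laboratory colony", "aquarium specimen")
  dom_sel <- wildness_s == "domesticated" & !ambiguous_s
  cap_sel <- wildness_s == "captive" & !ambiguous_s
  add_rows(dom_sel, dom_signals_key[prov$dom_sig],
           dom_signals_val[prov$dom_sig], 6)
  add_rows(cap_sel, cap_signals_key[prov$cap_sig],
           cap_signals_val[prov$cap_sig], 6)

  attributes <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$sample_accession, .data$type_ord) |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::mutate(ord = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$sample_accession,
                     key = harmonize_key(.data$key_raw),
                     .data$key_raw, .data$value, .data$ord)

  samples <- tibble::tibble(
    sample_accession = smp_acc,
    taxon_name = str_draw$taxon[ds_of_sample],
    taxon_id = NA_integer_,
    deposition_year = str_draw$dep_year[ds_of_sample])
  memberships <- tibble::tibble(dataset_accession = ds_acc[ds_of_sample],
                                sample_accession = smp_acc,
                                unlinked = FALSE)
  corpus <- new_corpus(samples, attributes, memberships,
                       provenance = sprintf("synthetic corpus (seed %d)",
                                            config$seed))

  truth <- tibble::tibble(
    sample_accession = smp_acc,
    dataset_accession = ds_acc[ds_of_sample],
    taxon_group = str_draw$group[ds_of_sample],
    has_coords = has_coords, has_year = has_year,
    true_latitude = ifelse(has_coords, val$lat, NA_real_),
    true_longitude = ifelse(has_coords, val$lon, NA_real_),
    true_year = ifelse(has_year, val$year, NA_integer_),
    coord_dialect = ifelse(has_coords, val$dialect, NA_character_),
    true_tier = true_tier,
    true_place = ifelse(place_present, val$place, NA_character_),
    true_country = ifelse(country_present, val$country, NA_character_),
    true_wildness = wildness_s,
    dataset_ambiguous = ambiguous_s,
    coord_masked = coord_masked, year_masked = year_masked,
    coord_misfiled = coord_misfiled, year_misfiled = year_misfiled,
    obs_coords = has_coords & !coord_masked,
    obs_year = has_year & !year_masked)

  dataset_truth <- tibble::tibble(
    dataset_accession = ds_acc,
    true_wildness = str_draw$wildness,
    is_wild = str_draw$wildness == "wild",
    ambiguous = str_draw$ambiguous,
    n_samples = str_draw$sizes)

  list(corpus = corpus, truth = truth, dataset_truth = dataset_truth,
       config = config)
}

#' A study-scale demonstration scenario
#'
#' Convenience scenario for end-to-end demonstration: ~3,000 datasets with
#' sample-level metadata presence set to coordinates 17%, years 41%, both
#' 14% (strongly dependent, as archives are), and the nonwild ambiguity
#' rate calibrated so the expected dataset-level precision of the wild
#' keyword filter is 0.70. Placeholder masking is off (absent fields still
#' emit placeholder tokens half the time) and 5% of present values are
#' misfiled, so with misfiled scanning enabled the audited coverage matches
#' the configured presence law.
#'
#' @param seed integer seed.
#' @param n_datasets number of datasets (default 3000).
#' @return as [generate_corpus()]: list with `corpus`, `truth`,
#'   `dataset_truth`, `config`.
#' @export
scenario_paper_mimic <- function(seed = 1L, n_datasets = 3000L) {
  w <- 0.55
  target_precision <- 0.70
  p_amb <- w * (1 / target_precision - 1) / (1 - w)
  config <- synthetic_config(
    n_datasets = n_datasets,
    size_mu = 8, size_disp = 1,
    p_coords = 0.17, p_year = 0.41,
    p_both_excess = 0.14 - 0.17 * 0.41,
    p_place_given_no_coords = 0.45,
    p_country_given_no_place = 0.5,
    p_placeholder = 0,
    p_misfiled = 0.05,
    wild_mixture = c(wild = w, domesticated = 0.30, captive = 0.15),
    p_ambiguous_provenance = p_amb,
    seed = seed)
  generate_corpus(config)
}
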