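#' Audit policy
#'
#' Controls how parsed metadata is turned into completeness statistics.
#'
#' @param count_zero_zero if `FALSE` (default), a (0, 0) coordinate does not
#'   count as "has coordinates" -- 0,0 is a common placeholder location and
#'   counting it would inflate coverage. Flagged records are reported
#'   separately either way.
#' @param rollup_rule how sample-level status rolls up to a dataset-level
#'   boolean: `"all"` (default; every member sample has the field),
#'   `"any"` (at least one member does), or `"proportion"` (at least
#'   `rollup_p` of members do). The phrasing "individuals in X% of datasets
#'   had ..." does not pin the rule down, so it is a first-class knob and
#'   summaries report the `all` and `any` readings side by side.
#' @param rollup_p threshold for the `"proportion"` rule.
#' @param cost_per_individual assumed sequencing cost per individual in USD
#'   (default 50), used by [estimate_lost_investment()].
#' @param cost_basis which samples count as "lost": `"not_both"` (default;
#'   everything outside the coordinates-and-year cell) or `"neither"`
#'   (samples with no spatial and no temporal metadata at all).
#' @return a list of class `audit_policy`.
#' @export
audit_policy <- function(count_zero_zero = FALSE,
                         rollup_rule = c("all", "any", "proportion"),
                         rollup_p = 0.5,
                         cost_per_individual = 50,
                         cost_basis = c("not_both", "neither")) {
  structure(list(count_zero_zero = isTRUE(count_zero_zero),
                 rollup_rule = match.arg(rollup_rule),
                 rollup_p = rollup_p,
                 cost_per_individual = cost_per_individual,
                 cost_basis = match.arg(cost_basis)),
            class = "audit_policy")
}

#' Classify per-sample metadata status
#'
#' Derives, for each parsed sample, the two booleans the audit pivots on --
#' has coordinates, has a collection year -- and the four-cell status
#' (`both`, `coords_only`, `year_only`, `neither`) that partitions any
#' sample set.
#'
#' @param parsed parsed-metadata tibble (`corpus$parsed` from
#'   [parse_corpus()], or one row per sample with `latitude`, `zero_zero`,
#'   `year`, `tier` columns).
#' @param policy an [audit_policy()].
#' @return the input with `has_coordinates`, `has_year`, `cell`,
#'   `location_tier` columns added.
#' @export
classify_sample_status <- function(parsed, policy = audit_policy()) {
  p <- tibble::as_tibble(parsed)
  p$has_coordinates <- !is.na(p$latitude) &
    (policy$count_zero_zero | !p$zero_zero)
  p$has_year <- !is.na(p$year)
  p$cell <- ifelse(p$has_coordinates & p$has_year, "both",
             ifelse(p$has_coordinates, "coords_only",
              ifelse(p$has_year, "year_only", "neither")))
  # a discounted (0,0) coordinate also cannot carry the coordinates tier
  p$location_tier <- ifelse(p$tier == "coordinates" & !p$has_coordinates,
                            ifelse(!is.na(p$place), "place_name",
                             ifelse(!is.na(p$country), "country", "none")),
                            p$tier)
  p
}

status_cells <- c("both", "coords_only", "year_only", "neither")

#' Roll sample status up to one dataset
#'
#' @param status tibble of member-sample statuses (columns
#'   `has_coordinates`, `has_year`, `cell`).
#' @param rule `"all"`, `"any"`, or `"proportion"`.
#' @param p threshold for the proportion rule.
#' @return one-row tibble: member count, fractions with
#'   coordinates/year/both, and the rule-based booleans.
#' @export
rollup_dataset <- function(status, rule = "all", p = 0.5) {
  if (nrow(status) == 0) stop("dataset has no member samples")
  if (!"location_tier" %in% names(status)) status$location_tier <- "none"
  frac_coords <- mean(status$has_coordinates)
  frac_year <- mean(status$has_year)
  frac_both <- mean(status$cell == "both")
  frac_loc_year <- mean(status$location_tier != "none" & status$has_year)
  thresh <- switch(rule, all = 1, any = 1e-12, proportion = p,
                   stop("unknown rollup rule: ", rule))
  tibble::tibble(
    n_samples = nrow(status),
    frac_with_coords = frac_coords, frac_with_year = frac_year,
    frac_with_both = frac_both,
    dataset_has_coords = frac_coords >= thresh,
    dataset_has_year = frac_year >= thresh,
    dataset_has_both = frac_both >= thresh,
    dataset_has_any_location_and_year = frac_loc_year >= thresh)
}

# sample-status master table: one row per (sample, dataset) membership plus
# per-sample wildness call and taxon group
sample_status_table <- function(corpus, policy, rules = scope_rules()) {
  if (is.null(corpus$parsed)) corpus <- parse_corpus(corpus)
  if (is.null(corpus$wildness)) corpus <- classify_corpus_wildness(corpus, rules)
  st <- classify_sample_status(corpus$parsed, policy)
  st |>
    dplyr::left_join(corpus$wildness[, c("sample_accession", "call")],
                     by = "sample_accession") |>
    dplyr::left_join(corpus$samples[, c("sample_accession", "taxon_name",
                                        "deposition_year")],
                     by = "sample_accession") |>
    dplyr::mutate(taxon_group = assign_taxon_group(.data$taxon_name, rules))
}

#' Roll up every dataset in a corpus
#'
#' @param corpus a parsed, wildness-classified corpus.
#' @param policy an [audit_policy()]; `rule` defaults to its rollup rule.
#' @param rule,p override the policy's rollup rule.
#' @param wild_only restrict member samples to putatively wild ones (and
#'   drop datasets with no wild members).
#' @param rules a [scope_rules()] (used if wildness must be computed).
#' @return tibble with one row per linked dataset.
#' @export
rollup_datasets <- function(corpus, policy = audit_policy(),
                            rule = policy$rollup_rule, p = policy$rollup_p,
                            wild_only = FALSE, rules = scope_rules()) {
  st <- sample_status_table(corpus, policy, rules)
  mem <- corpus$memberships[!corpus$memberships$unlinked, , drop = FALSE]
  tab <- dplyr::inner_join(mem, st, by = "sample_accession")
  if (wild_only) tab <- tab[tab$call == "wild", , drop = FALSE]
  if (nrow(tab) == 0) {
    return(tibble::tibble(dataset_accession = character(), n_samples = integer(),
                          n_wild = integer(), frac_with_coords = double(),
                          frac_with_year = double(), frac_with_both = double(),
                          dataset_has_coords = logical(),
                          dataset_has_year = logical(),
                          dataset_has_both = logical(),
                          dataset_has_any_location_and_year = logical()))
  }
  thresh <- switch(rule, all = 1, any = 1e-12, proportion = p,
                   stop("unknown rollup rule: ", rule))
  tab |>
    dplyr::group_by(.data$dataset_accession) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_wild = sum(.data$call == "wild"),
      frac_with_coords = mean(.data$has_coordinates),
      frac_with_year = mean(.data$has_year),
      frac_with_both = mean(.data$cell == "both"),
      frac_loc_year = mean(.data$location_tier != "none" & .data$has_year),
      .groups = "drop") |>
    dplyr::mutate(
      dataset_has_coords = .data$frac_with_coords >= thresh,
      dataset_has_year = .data$frac_with_year >= thresh,
      dataset_has_both = .data$frac_with_both >= thresh,
      dataset_has_any_location_and_year = .data$frac_loc_year >= thresh) |>
    dplyr::select(-"frac_loc_year") |>
    dplyr::arrange(.data$dataset_accession)
}

#' Select conservation-priority datasets
#'
#' Datasets describing more than four putatively wild individuals (i.e. at
#' least five) are the ones worth labor-intensive external metadata
#' recovery; a dataset with exactly four wild members is excluded.
#'
#' @param corpus a wildness-classified corpus.
#' @param min_wild strict lower bound on the wild member count (default 4:
#'   "more than four").
#' @param rules a [scope_rules()] (used if wildness must be computed).
#' @return tibble of selected datasets (`dataset_accession`, `n_samples`,
#'   `n_wild`), ordered by accession.
#' @export
select_priority_datasets <- function(corpus, min_wild = 4,
                                     rules = scope_rules()) {
  if (is.null(corpus$wildness)) corpus <- classify_corpus_wildness(corpus, rules)
  mem <- corpus$memberships[!corpus$memberships$unlinked, , drop = FALSE]
  mem |>
    dplyr::inner_join(corpus$wildness, by = "sample_accession") |>
    dplyr::group_by(.data$dataset_accession) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_wild = sum(.data$call == "wild"), .groups = "drop") |>
    dplyr::filter(.data$n_wild > min_wild) |>
    dplyr::arrange(.data$dataset_accession)
}

#' Summarize metadata completeness for a corpus
#'
#' The central audit: per-sample status cells, location tiers, dataset
#' rollups under the `all` and `any` readings, wild/domesticated/captive
#' breakdowns, taxon-group and deposition-year cross-tabs, and the
#' cost-of-loss inputs. Proportions over an empty denominator are reported
#' as `NA` (undefined), never as 0.
#'
#' @param corpus an `insdc_corpus` (parsed and classified on demand).
#' @param policy an [audit_policy()].
#' @param rules a [scope_rules()].
#' @return object of class `audit_summary`.
#' @export
summarize_corpus <- function(corpus, policy = audit_policy(),
                             rules = scope_rules()) {
  if (is.null(corpus$parsed)) corpus <- parse_corpus(corpus)
  if (is.null(corpus$wildness)) corpus <- classify_corpus_wildness(corpus, rules)
  st <- sample_status_table(corpus, policy, rules)
  n <- nrow(st)
  prop <- function(x, d = n) if (d > 0) x / d else NA_real_

  cell_counts <- function(tab) {
    counts <- table(factor(tab$cell, levels = status_cells))
    tibble::tibble(cell = status_cells, n = as.integer(counts),
                   proportion = if (nrow(tab) > 0)
                     as.numeric(counts) / nrow(tab) else NA_real_)
  }
  cells_overall <- cell_counts(st)
  cells_by_call <- lapply(split(st, st$call), cell_counts)

  tier_year <- st |>
    dplyr::count(tier = factor(.data$location_tier,
                               levels = c("coordinates", "place_name",
                                          "country", "none")),
                 has_year = .data$has_year, .drop = FALSE) |>
    dplyr::mutate(tier = as.character(.data$tier))

  ds_all <- rollup_datasets(corpus, policy, rule = "all")
  ds_any <- rollup_datasets(corpus, policy, rule = "any")
  ds_active <- rollup_datasets(corpus, policy)
  # programmatically wild datasets: every member sample classified wild
  wild_ds <- ds_all[ds_all$n_wild == ds_all$n_samples, , drop = FALSE]

  ds_props <- function(d) {
    m <- nrow(d)
    tibble::tibble(
      n_datasets = m,
      prop_coords = if (m) mean(d$dataset_has_coords) else NA_real_,
      prop_year = if (m) mean(d$dataset_has_year) else NA_real_,
      prop_both = if (m) mean(d$dataset_has_both) else NA_real_,
      prop_any_location_and_year = if (m)
        mean(d$dataset_has_any_location_and_year) else NA_real_)
  }

  taxon_tab <- st |>
    dplyr::count(.data$taxon_group, .data$cell) |>
    dplyr::arrange(.data$taxon_group, .data$cell)
  year_tab <- st |>
    dplyr::count(.data$deposition_year, .data$cell) |>
    dplyr::arrange(.data$deposition_year, .data$cell)

  n_wild_samples <- sum(st$call == "wild")
  n_missing_both <- n - sum(st$cell == "both")
  n_missing_either <- sum(st$cell == "neither")
  mem <- corpus$memberships[!corpus$memberships$unlinked, , drop = FALSE]

  structure(list(
    totals = list(
      n_samples = n,
      n_datasets = length(unique(mem$dataset_accession)),
      n_unlinked_samples = sum(corpus$memberships$unlinked),
      n_wild_samples = n_wild_samples,
      n_domesticated_samples = sum(st$call == "domesticated"),
      n_captive_samples = sum(st$call == "captive"),
      n_wild_datasets = nrow(wild_ds),
      n_zero_zero = sum(st$zero_zero, na.rm = TRUE),
      n_coord_promoted = sum(st$coord_origin %in% "misfiled"),
      n_year_promoted = sum(st$year_origin %in% "misfiled"),
      n_missing_both = n_missing_both,
      n_missing_either = n_missing_either),
    proportions = list(
      sample_coords = prop(sum(st$has_coordinates)),
      sample_year = prop(sum(st$has_year)),
      sample_both = prop(sum(st$cell == "both")),
      sample_place_or_better = prop(sum(st$location_tier %in%
                                          c("coordinates", "place_name"))),
      sample_country_or_better = prop(sum(st$location_tier != "none")),
      sample_some_location_and_year = prop(sum(st$location_tier != "none" &
                                                 st$has_year)),
      wild_sample_both = prop(sum(st$cell == "both" & st$call == "wild"),
                              n_wild_samples)),
    cells = cells_overall,
    cells_by_call = cells_by_call,
    tier_year = tier_year,
    datasets = ds_active,
    dataset_props = list(all = ds_props(ds_all), any = ds_props(ds_any),
                         active = ds_props(ds_active),
                         wild_all = ds_props(wild_ds)),
    taxon_table = taxon_tab,
    year_table = year_tab,
    samples = st,
    policy = policy),
    class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  t <- x$totals; p <- x$proportions
  cat("<audit_summary> ", t$n_samples, " samples in ", t$n_datasets,
      " datasets (", t$n_wild_samples, " putatively wild samples)\n", sep = "")
  cat(sprintf("  coordinates: %.1f%%   year: %.1f%%   both: %.1f%%\n",
              100 * p$sample_coords, 100 * p$sample_year, 100 * p$sample_both))
  invisible(x)
}

#' Estimate the investment lost to missing metadata
#'
#' Sequenced individuals whose records lack usable spatiotemporal metadata
#' represent sunk sequencing cost with no reuse value for diversity
#' monitoring. The estimate multiplies the count of such samples by an
#' assumed per-individual sequencing cost (default USD 50).
#'
#' @param summary an `audit_summary`.
#' @param cost_per_individual cost per sequenced individual in USD; must be
#'   non-negative.
#' @param basis `"not_both"` (default: samples outside the
#'   coordinates-and-year cell are lost) or `"neither"` (only samples with
#'   no spatiotemporal metadata at all).
#' @return list of class `lost_investment`: `amount` (USD), `n_missing`,
#'   `cost_per_individual`, `basis`.
#' @examples
#' \dontrun{estimate_lost_investment(summarize_corpus(corpus))}
#' @export
estimate_lost_investment <- function(summary,
                                     cost_per_individual = summary$policy$cost_per_individual,
                                     basis = summary$policy$cost_basis) {
  if (cost_per_individual < 0) stop("cost_per_individual must be non-negative")
  n_missing <- switch(basis,
                      not_both = summary$totals$n_missing_both,
                      neither = summary$totals$n_missing_either,
                      stop("unknown cost basis: ", basis))
  structure(list(amount = n_missing * cost_per_individual,
                 n_missing = n_missing,
                 cost_per_individual = cost_per_individual,
                 basis = basis,
                 assumptions = paste0("USD ", cost_per_individual,
                                      " per sequenced individual; missing = ",
                                      basis)),
            class = "lost_investment")
}

#' @export
print.lost_investment <- function(x, ...) {
  cat(sprintf("lost investment: $%s (%s samples x $%s; basis %s)\n",
              format(x$amount, big.mark = ","),
              format(x$n_missing, big.mark = ","),
              x$cost_per_individual, x$basis))
  invisible(x)
}

#' Cumulative deposition growth by status
#'
#' Counts samples by deposition year and status cell and accumulates over
#' years -- the table behind a stacked archive-growth plot. Samples with an
#' unknown deposition year go to a separate bin and are excluded from the
#' cumulative curve.
#'
#' @param corpus an `insdc_corpus`.
#' @param policy an [audit_policy()].
#' @param rules a [scope_rules()].
#' @return tibble: `deposition_year`, `cell`, `n`, `cumulative`; the
#'   unknown-year bin is attached as attribute `"unknown"`.
#' @export
summarize_growth <- function(corpus, policy = audit_policy(),
                             rules = scope_rules()) {
  st <- sample_status_table(corpus, policy, rules)
  known <- st[!is.na(st$deposition_year), , drop = FALSE]
  unknown <- st[is.na(st$deposition_year), , drop = FALSE]
  if (nrow(known) == 0) {
    out <- tibble::tibble(deposition_year = integer(), cell = character(),
                          n = integer(), cumulative = integer())
  } else {
    yrs <- seq(min(known$deposition_year), max(known$deposition_year))
    out <- known |>
      dplyr::count(.data$deposition_year, .data$cell) |>
      tidyr::complete(deposition_year = yrs,
                      cell = status_cells, fill = list(n = 0L)) |>
      dplyr::arrange(.data$cell, .data$deposition_year) |>
      dplyr::group_by(.data$cell) |>
      dplyr::mutate(cumulative = cumsum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$deposition_year, .data$cell)
  }
  attr(out, "unknown") <- unknown |> dplyr::count(.data$cell)
  out
}

#' Write audit summary tables
#'
#' Emits deterministic TSV tables (per-sample status, per-dataset status,
#' tier proportions, taxon-group and per-year cross-tabs) plus one JSON
#' report of all counts and proportions. Byte-identical across runs on
#' identical input.
#'
#' @param summary an `audit_summary`.
#' @param growth optional growth table from [summarize_growth()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the file paths written.
#' @export
write_audit_tables <- function(summary, out_dir, growth = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  paths <- character(0)
  wr <- function(tab, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tab, p, na = "", progress = FALSE)
    paths <<- c(paths, p)
  }
  per_sample <- summary$samples |>
    dplyr::arrange(.data$sample_accession) |>
    dplyr::select("sample_accession", "has_coordinates", "has_year", "cell",
                  "location_tier", "country", "place", "call", "taxon_group",
                  "deposition_year")
  wr(per_sample, "per_sample_status.tsv")
  wr(summary$datasets, "per_dataset_status.tsv")
  wr(summary$cells, "tier_proportions.tsv")
  wr(summary$taxon_table, "taxon_group_status.tsv")
  if (!is.null(growth)) wr(growth, "growth_by_year.tsv")
  report <- list(totals = summary$totals,
                 proportions = summary$proportions,
                 dataset_props = summary$dataset_props)
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "columns")
  paths <- c(paths, jp)
  paths
}
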