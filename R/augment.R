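#' Read an augmentation table
#'
#' Externally recovered metadata (typically scoured from the publications
#' associated with each dataset) is supplied as a TSV with columns
#' `sample_accession`, `dataset_accession`, `latitude`, `longitude`,
#' `collection_year`, `place`, `country`, `source_citation`. A row may name
#' a single sample or (with an empty `sample_accession`) a whole dataset,
#' in which case it applies to every member sample.
#'
#' @param path path to the TSV file.
#' @return tibble of augmentation rows.
#' @export
read_augmentation_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_accession = readr::col_character(),
    dataset_accession = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    collection_year = readr::col_integer(),
    place = readr::col_character(),
    country = readr::col_character(),
    source_citation = readr::col_character()),
    na = c("", "NA"), progress = FALSE)
}

#' Merge externally recovered metadata into a corpus
#'
#' Recovered values fill *empty* slots only: a value already derived from
#' the archive (including one promoted from a misfiled field) is never
#' overwritten, and the conflict is logged instead. Every filled slot is
#' tagged with origin `"augmentation"` so before/after summaries can
#' separate archive-present from recovered metadata. Recovered coordinates
#' and years must satisfy the same validity windows as parsed values;
#' invalid rows are rejected with a reason. Rows naming an accession absent
#' from the corpus raise an error listing the offenders.
#'
#' @param corpus a parsed `insdc_corpus`.
#' @param table augmentation tibble (see [read_augmentation_table()]).
#' @return the corpus with updated `parsed` and an `augmentation_log`
#'   component (tibbles `conflicts` and `rejected`).
#' @export
apply_augmentation <- function(corpus, table) {
  if (is.null(corpus$parsed)) corpus <- parse_corpus(corpus)
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) {
    corpus$augmentation_log <- list(
      conflicts = tibble::tibble(sample_accession = character(),
                                 field = character(),
                                 archive_value = character(),
                                 recovered_value = character()),
      rejected = tibble::tibble(row = integer(), reason = character()))
    return(corpus)
  }

  has_sample <- !is.na(table$sample_accession) & nzchar(table$sample_accession)
  bad_s <- setdiff(table$sample_accession[has_sample],
                   corpus$samples$sample_accession)
  bad_d <- setdiff(table$dataset_accession[!has_sample],
                   corpus$memberships$dataset_accession)
  if (length(bad_s) || length(bad_d)) {
    stop("augmentation rows reference unknown accessions: ",
         paste(head(c(bad_s, bad_d), 10), collapse = ", "))
  }

  # validity: coordinates in range (both present), year in window
  reject <- rep(NA_character_, nrow(table))
  has_coord <- !is.na(table$latitude) | !is.na(table$longitude)
  bad_coord <- has_coord & (is.na(table$latitude) | is.na(table$longitude) |
                              abs(table$latitude) > 90 |
                              abs(table$longitude) > 180)
  reject[bad_coord] <- "invalid_coordinate"
  bad_year <- !is.na(table$collection_year) &
    (table$collection_year < 1800 | table$collection_year > current_year())
  reject[is.na(reject) & bad_year] <- "invalid_year"
  rejected <- tibble::tibble(row = which(!is.na(reject)),
                             reason = reject[!is.na(reject)])
  table <- table[is.na(reject), , drop = FALSE]

  # expand dataset-level rows to member samples
  has_sample <- !is.na(table$sample_accession) & nzchar(table$sample_accession)
  per_sample <- table[has_sample, , drop = FALSE]
  per_dataset <- table[!has_sample, , drop = FALSE]
  if (nrow(per_dataset)) {
    expanded <- per_dataset |>
      dplyr::select(-"sample_accession") |>
      dplyr::inner_join(corpus$memberships[, c("dataset_accession",
                                               "sample_accession")],
                        by = "dataset_accession")
    per_sample <- dplyr::bind_rows(per_sample, expanded)
  }
  # one recovered value per sample per field: first row wins
  per_sample <- per_sample |>
    dplyr::distinct(.data$sample_accession, .keep_all = TRUE)

  p <- corpus$parsed
  i <- match(per_sample$sample_accession, p$sample_accession)
  conflicts <- list()
  log_conflict <- function(sel, field, archive, recovered) {
    if (!any(sel)) return(NULL)
    tibble::tibble(sample_accession = per_sample$sample_accession[sel],
                   field = field,
                   archive_value = as.character(archive[sel]),
                   recovered_value = as.character(recovered[sel]))
  }

  want_coord <- !is.na(per_sample$latitude)
  slot_empty <- is.na(p$latitude[i])
  fill <- want_coord & slot_empty
  conflicts$coord <- log_conflict(want_coord & !slot_empty, "coordinate",
                                  p$latitude[i], per_sample$latitude)
  p$latitude[i[fill]] <- round(per_sample$latitude[fill], 6)
  p$longitude[i[fill]] <- round(per_sample$longitude[fill], 6)
  p$coord_origin[i[fill]] <- "augmentation"
  p$coord_source_key[i[fill]] <- "augmentation"
  p$zero_zero[i[fill]] <- p$latitude[i[fill]] == 0 & p$longitude[i[fill]] == 0

  want_year <- !is.na(per_sample$collection_year)
  slot_empty <- is.na(p$year[i])
  fill <- want_year & slot_empty
  conflicts$year <- log_conflict(want_year & !slot_empty, "year",
                                 p$year[i], per_sample$collection_year)
  p$year[i[fill]] <- per_sample$collection_year[fill]
  p$year_precision[i[fill]] <- "year"
  p$year_origin[i[fill]] <- "augmentation"
  p$year_source_key[i[fill]] <- "augmentation"

  for (field in c("place", "country")) {
    want <- !is.na(per_sample[[field]])
    slot_empty <- is.na(p[[field]][i])
    fill <- want & slot_empty
    conflicts[[field]] <- log_conflict(want & !slot_empty, field,
                                       p[[field]][i], per_sample[[field]])
    p[[field]][i[fill]] <- per_sample[[field]][fill]
  }

  p$tier <- ifelse(!is.na(p$latitude), "coordinates",
             ifelse(!is.na(p$place), "place_name",
              ifelse(!is.na(p$country), "country", "none")))
  corpus$parsed <- p
  corpus$augmentation_log <- list(
    conflicts = dplyr::bind_rows(conflicts),
    rejected = rejected)
  corpus
}
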