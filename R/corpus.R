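#' Build a record corpus
#'
#' A corpus bundles sample records (one per sequenced individual, BioSample
#' style) with their free-text attributes and their membership in datasets
#' (BioProject style). It is the unit every downstream stage -- parsing,
#' wildness classification, auditing, validation -- operates on.
#'
#' @param samples tibble with columns `sample_accession`, `taxon_name`,
#'   `taxon_id` (integer, may be `NA`), `deposition_year` (integer, may be
#'   `NA`). Extra columns are preserved.
#' @param attributes tibble with columns `sample_accession`, `key`
#'   (harmonized), `key_raw` (original spelling), `value`, `ord` (1-based
#'   position within the sample's attribute list). Duplicate keys are
#'   permitted and all retained; values are stored verbatim apart from
#'   surrounding whitespace.
#' @param memberships tibble with columns `dataset_accession`,
#'   `sample_accession`, `unlinked` (logical; `TRUE` for the synthetic
#'   singleton dataset created when a sample carries no dataset link).
#' @param provenance free-text description of where the records came from.
#' @param n_skipped count of input records skipped at read time (e.g. missing
#'   accession).
#' @return object of class `insdc_corpus`.
#' @export
new_corpus <- function(samples, attributes, memberships,
                       provenance = "", n_skipped = 0L) {
  samples <- tibble::as_tibble(samples)
  attributes <- tibble::as_tibble(attributes)
  memberships <- tibble::as_tibble(memberships)
  if (!"unlinked" %in% names(memberships)) memberships$unlinked <- FALSE
  corpus <- structure(
    list(samples = samples, attributes = attributes,
         memberships = memberships, provenance = provenance,
         n_skipped = as.integer(n_skipped)),
    class = "insdc_corpus")
  validate_corpus(corpus)
}

#' Validate corpus invariants
#'
#' Checks that sample accessions are unique, every membership and attribute
#' row resolves to a sample, every sample belongs to at least one dataset,
#' and deposition years (when present) fall in `[1982, current year]` --
#' the INSDC did not exist before the early 1980s.
#'
#' @param corpus an `insdc_corpus`.
#' @return the corpus, invisibly usable in pipes; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  s <- corpus$samples
  if (anyDuplicated(s$sample_accession)) {
    dup <- unique(s$sample_accession[duplicated(s$sample_accession)])
    stop("duplicate sample accessions: ", paste(head(dup, 5), collapse = ", "))
  }
  if (nrow(corpus$memberships)) {
    bad <- setdiff(corpus$memberships$sample_accession, s$sample_accession)
    if (length(bad)) {
      stop("membership rows reference unknown samples: ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  if (nrow(s)) {
    orphan <- setdiff(s$sample_accession, corpus$memberships$sample_accession)
    if (length(orphan)) {
      stop("samples without any dataset membership: ",
           paste(head(orphan, 5), collapse = ", "))
    }
  }
  if (nrow(corpus$attributes)) {
    bad <- setdiff(corpus$attributes$sample_accession, s$sample_accession)
    if (length(bad)) {
      stop("attribute rows reference unknown samples: ",
           paste(head(bad, 5), collapse = ", "))
    }
    if (any(!nzchar(trimws(corpus$attributes$key)))) {
      stop("attribute keys must be non-empty after trimming")
    }
  }
  yr <- s$deposition_year
  bad_yr <- !is.na(yr) & (yr < 1982L | yr > current_year())
  if (any(bad_yr)) {
    stop("deposition_year outside [1982, current year] for: ",
         paste(head(s$sample_accession[bad_yr], 5), collapse = ", "))
  }
  corpus
}

current_year <- function() as.integer(format(Sys.Date(), "%Y"))

#' @export
print.insdc_corpus <- function(x, ...) {
  ds <- corpus_datasets(x)
  cat("<insdc_corpus> ", nrow(x$samples), " samples, ",
      nrow(ds), " datasets (", sum(ds$unlinked), " unlinked), ",
      nrow(x$attributes), " attribute rows\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  if (x$n_skipped > 0) cat("records skipped at read: ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

#' Dataset-level view of a corpus
#'
#' @param corpus an `insdc_corpus`.
#' @return tibble with one row per dataset: `dataset_accession`, `n_samples`,
#'   `unlinked`.
#' @export
corpus_datasets <- function(corpus) {
  corpus$memberships |>
    dplyr::group_by(.data$dataset_accession) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     unlinked = any(.data$unlinked), .groups = "drop") |>
    dplyr::arrange(.data$dataset_accession)
}

#' Attributes of one sample, in deposition order
#'
#' @param corpus an `insdc_corpus`.
#' @param sample_accession one sample accession.
#' @return tibble of that sample's attribute rows ordered by `ord`.
#' @export
sample_attributes <- function(corpus, sample_accession) {
  acc <- sample_accession
  corpus$attributes |>
    dplyr::filter(.data$sample_accession == acc) |>
    dplyr::arrange(.data$ord)
}

flat_table_columns <- c("sample_accession", "dataset_accession", "taxon_name",
                        "taxon_id", "deposition_year", "attr_key", "attr_value")

#' Read a flat attribute table into a corpus
#'
#' The flat format is a UTF-8 TSV with header columns `sample_accession`,
#' `dataset_accession`, `taxon_name`, `taxon_id`, `deposition_year`,
#' `attr_key`, `attr_value` and one row per attribute. Rows are grouped by
#' sample; a sample appearing under several dataset accessions belongs to all
#' of them. Rows with an empty `attr_key` carry no attribute (they exist only
#' to declare a sample or an extra dataset membership). Empty `attr_value`
#' rows are retained verbatim -- placeholder detection happens in the parsers.
#'
#' @param path path to the TSV file.
#' @return an `insdc_corpus`.
#' @export
read_flat_table <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), quote = "", progress = FALSE)
  missing_cols <- setdiff(flat_table_columns, names(tab))
  if (length(missing_cols)) {
    stop("flat table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab$taxon_id <- suppressWarnings(as.integer(tab$taxon_id))
  tab$deposition_year <- suppressWarnings(as.integer(tab$deposition_year))
  if (nrow(tab) == 0) {
    return(new_corpus(
      samples = tibble::tibble(sample_accession = character(),
                               taxon_name = character(),
                               taxon_id = integer(),
                               deposition_year = integer()),
      attributes = empty_attributes(),
      memberships = tibble::tibble(dataset_accession = character(),
                                   sample_accession = character(),
                                   unlinked = logical()),
      provenance = paste0("flat table: ", path)))
  }
  taxon_chk <- tab |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::summarise(n_tax = dplyr::n_distinct(.data$taxon_name), .groups = "drop")
  if (any(taxon_chk$n_tax > 1)) {
    stop("inconsistent taxon_name across rows of sample(s): ",
         paste(head(taxon_chk$sample_accession[taxon_chk$n_tax > 1], 5),
               collapse = ", "))
  }
  samples <- tab |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::summarise(taxon_name = .data$taxon_name[1],
                     taxon_id = .data$taxon_id[1],
                     deposition_year = .data$deposition_year[1],
                     .groups = "drop")
  has_attr <- nzchar(trimws(tab$attr_key))
  attributes <- tab[has_attr, ] |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::mutate(ord = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$sample_accession,
                     key = harmonize_key(.data$attr_key),
                     key_raw = .data$attr_key,
                     value = trimws(.data$attr_value),
                     .data$ord)
  memberships <- make_memberships(tab$sample_accession, tab$dataset_accession)
  new_corpus(samples, attributes, memberships,
             provenance = paste0("flat table: ", path))
}

empty_attributes <- function() {
  tibble::tibble(sample_accession = character(), key = character(),
                 key_raw = character(), value = character(), ord = integer())
}

# distinct (sample, dataset) pairs; blank dataset -> unlinked singleton
make_memberships <- function(sample_accession, dataset_accession) {
  ds <- trimws(as.character(dataset_accession))
  unlinked <- is.na(ds) | !nzchar(ds)
  ds[unlinked] <- paste0("UNLINKED:", sample_accession[unlinked])
  dplyr::distinct(tibble::tibble(dataset_accession = ds,
                                 sample_accession = sample_accession,
                                 unlinked = unlinked))
}

#' Write a corpus to the flat table format
#'
#' Inverse of [read_flat_table()]: attributes are written under the sample's
#' first dataset accession; each additional dataset membership gets one
#' attribute-less row. Output is deterministic (sorted by sample accession,
#' attribute order preserved), so identical corpora yield byte-identical
#' files.
#'
#' @param corpus an `insdc_corpus`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(corpus, path) {
  mem <- corpus$memberships |>
    dplyr::mutate(dataset_out = ifelse(.data$unlinked, "", .data$dataset_accession)) |>
    dplyr::arrange(.data$sample_accession, .data$dataset_accession) |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::mutate(mem_rank = dplyr::row_number()) |>
    dplyr::ungroup()
  first_ds <- mem |> dplyr::filter(.data$mem_rank == 1) |>
    dplyr::select("sample_accession", "dataset_out")
  base <- corpus$samples |> dplyr::left_join(first_ds, by = "sample_accession")
  attr_rows <- corpus$attributes |>
    dplyr::left_join(base, by = "sample_accession") |>
    dplyr::transmute(.data$sample_accession,
                     dataset_accession = .data$dataset_out,
                     .data$taxon_name, .data$taxon_id, .data$deposition_year,
                     attr_key = .data$key_raw, attr_value = .data$value,
                     .data$ord)
  bare <- base |>
    dplyr::anti_join(corpus$attributes, by = "sample_accession") |>
    dplyr::transmute(.data$sample_accession,
                     dataset_accession = .data$dataset_out,
                     .data$taxon_name, .data$taxon_id, .data$deposition_year,
                     attr_key = "", attr_value = "", ord = 0L)
  extra <- mem |> dplyr::filter(.data$mem_rank > 1) |>
    dplyr::left_join(corpus$samples, by = "sample_accession") |>
    dplyr::transmute(.data$sample_accession,
                     dataset_accession = .data$dataset_out,
                     .data$taxon_name, .data$taxon_id, .data$deposition_year,
                     attr_key = "", attr_value = "", ord = 1000000L)
  out <- dplyr::bind_rows(attr_rows, bare, extra) |>
    dplyr::arrange(.data$sample_accession, .data$ord) |>
    dplyr::select(dplyr::all_of(flat_table_columns))
  # no quoting/escaping: attribute values are free text that may contain
  # quotes, and the format forbids embedded tabs/newlines
  readr::write_tsv(out, path, na = "", progress = FALSE,
                   quote = "none", escape = "none")
  invisible(path)
}

#' Read a BioSample-style XML file into a corpus
#'
#' Reads the NCBI BioSample XML dialect: a `BioSampleSet` root holding
#' `BioSample` elements with an `accession` attribute, an
#' `Description/Organism` element (taxon name and id), `Attributes/Attribute`
#' children (original key in `attribute_name`, harmonized key in
#' `harmonized_name` when present), and `Links/Link` elements with
#' `target="bioproject"` naming the dataset. Samples with no dataset link are
#' placed in a synthetic singleton dataset flagged unlinked. BioSample
#' elements lacking an accession are skipped with a warning and counted in
#' the corpus skip tally.
#'
#' @param path path to the XML file.
#' @return an `insdc_corpus`.
#' @export
read_biosample_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in ", path, ": ", conditionMessage(e))
  })
  nodes <- xml2::xml_find_all(doc, "//BioSample")
  skipped <- 0L
  samples <- list(); attrs <- list(); mems <- list()
  for (node in nodes) {
    acc <- xml2::xml_attr(node, "accession")
    if (is.na(acc) || !nzchar(trimws(acc))) {
      skipped <- skipped + 1L
      warning("BioSample element without accession skipped", call. = FALSE)
      next
    }
    org <- xml2::xml_find_first(node, ".//Description/Organism")
    taxon_name <- if (inherits(org, "xml_missing")) NA_character_ else
      xml2::xml_attr(org, "taxonomy_name")
    taxon_id <- if (inherits(org, "xml_missing")) NA_integer_ else
      suppressWarnings(as.integer(xml2::xml_attr(org, "taxonomy_id")))
    sub_date <- xml2::xml_attr(node, "submission_date")
    dep_year <- if (is.na(sub_date)) NA_integer_ else
      suppressWarnings(as.integer(substr(sub_date, 1, 4)))
    a_nodes <- xml2::xml_find_all(node, ".//Attributes/Attribute")
    if (length(a_nodes)) {
      key_raw <- xml2::xml_attr(a_nodes, "attribute_name")
      harm <- xml2::xml_attr(a_nodes, "harmonized_name")
      key <- ifelse(is.na(harm), harmonize_key(key_raw), harmonize_key(harm))
      attrs[[acc]] <- tibble::tibble(
        sample_accession = acc, key = key, key_raw = key_raw,
        value = trimws(xml2::xml_text(a_nodes)),
        ord = seq_along(a_nodes))
    }
    links <- xml2::xml_find_all(node,
      ".//Links/Link[@target='bioproject']")
    ds <- unique(c(xml2::xml_attr(links, "label"),
                   if (length(links)) trimws(xml2::xml_text(links))))
    ds <- ds[!is.na(ds) & nzchar(ds)]
    mems[[acc]] <- tibble::tibble(
      dataset_accession = if (length(ds)) ds else "",
      sample_accession = acc)
    samples[[acc]] <- tibble::tibble(
      sample_accession = acc, taxon_name = taxon_name,
      taxon_id = taxon_id, deposition_year = dep_year)
  }
  if (!length(samples)) {
    return(new_corpus(
      samples = tibble::tibble(sample_accession = character(),
                               taxon_name = character(), taxon_id = integer(),
                               deposition_year = integer()),
      attributes = empty_attributes(),
      memberships = tibble::tibble(dataset_accession = character(),
                                   sample_accession = character(),
                                   unlinked = logical()),
      provenance = paste0("biosample xml: ", path), n_skipped = skipped))
  }
  mem_tab <- dplyr::bind_rows(mems)
  new_corpus(
    samples = dplyr::bind_rows(samples),
    attributes = if (length(attrs)) dplyr::bind_rows(attrs) else empty_attributes(),
    memberships = make_memberships(mem_tab$sample_accession,
                                   mem_tab$dataset_accession),
    provenance = paste0("biosample xml: ", path), n_skipped = skipped)
}

#' Write a corpus in the BioSample XML dialect
#'
#' Emits the same `BioSampleSet` structure [read_biosample_xml()] consumes;
#' used by the synthetic corpus emitter and by reader-equivalence tests.
#'
#' @param corpus an `insdc_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biosample_xml <- function(corpus, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  smp <- corpus$samples |> dplyr::arrange(.data$sample_accession)

  # pre-render per-sample fragments vectorized, then assemble in order
  attr_line <- corpus$attributes |>
    dplyr::arrange(.data$sample_accession, .data$ord) |>
    dplyr::mutate(line = sprintf(
      '    <Attribute attribute_name="%s" harmonized_name="%s">%s</Attribute>',
      esc(.data$key_raw), esc(.data$key), esc(.data$value)))
  attr_block <- attr_line |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::summarise(block = paste0("  <Attributes>\n",
                                    paste(.data$line, collapse = "\n"),
                                    "\n  </Attributes>"), .groups = "drop")
  link_line <- corpus$memberships[!corpus$memberships$unlinked, , drop = FALSE] |>
    dplyr::arrange(.data$sample_accession, .data$dataset_accession) |>
    dplyr::mutate(line = sprintf(
      '    <Link type="entrez" target="bioproject" label="%s">%s</Link>',
      esc(.data$dataset_accession), esc(.data$dataset_accession)))
  link_block <- link_line |>
    dplyr::group_by(.data$sample_accession) |>
    dplyr::summarise(block = paste0("  <Links>\n",
                                    paste(.data$line, collapse = "\n"),
                                    "\n  </Links>"), .groups = "drop")

  open_tag <- ifelse(is.na(smp$deposition_year),
                     sprintf('<BioSample accession="%s">',
                             esc(smp$sample_accession)),
                     sprintf('<BioSample accession="%s" submission_date="%d-01-01">',
                             esc(smp$sample_accession), smp$deposition_year))
  org_attrs <- paste0(
    ifelse(is.na(smp$taxon_name), "",
           sprintf(' taxonomy_name="%s"', esc(smp$taxon_name))),
    ifelse(is.na(smp$taxon_id), "",
           sprintf(' taxonomy_id="%d"', smp$taxon_id)))
  desc <- sprintf("  <Description><Organism%s/></Description>", org_attrs)

  ab <- attr_block$block[match(smp$sample_accession,
                               attr_block$sample_accession)]
  lb <- link_block$block[match(smp$sample_accession,
                               link_block$sample_accession)]
  body <- paste0(open_tag, "\n", desc,
                 ifelse(is.na(ab), "", paste0("\n", ab)),
                 ifelse(is.na(lb), "", paste0("\n", lb)),
                 "\n</BioSample>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>', "<BioSampleSet>",
               body, "</BioSampleSet>"), con, useBytes = FALSE)
  invisible(path)
}
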