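#' Rule set for scope filtering and wildness classification
#'
#' Encodes, as data, the filter logic that separates wild from domesticated
#' and captive material and restricts the audit to genomic-level eukaryote
#' records. The packaged defaults are a documented reconstruction of the
#' kind of filter a biodiversity audit uses -- archives carry no "wild"
#' flag, so wildness must be inferred from taxon lists and keyword signals
#' -- and every list is configurable.
#'
#' `"strain"` alone never triggers a domesticated call (it is ubiquitous in
#' microbiology and model-organism records); it only adds evidence when a
#' core domestication keyword co-occurs on the record.
#'
#' @param domesticated_taxa taxon names treated as domesticated at species
#'   level; this overrides per-sample keywords (a species-level exclusion).
#' @param domestication_keywords words (matched case-insensitively on word
#'   boundaries in attribute keys and values) signalling domesticated
#'   material.
#' @param captivity_keywords words signalling captive (but not
#'   domesticated) material: zoo animals, lab colonies, cultured isolates.
#'   Must be disjoint from the domestication set.
#' @param context_keywords words that count only alongside a domestication
#'   keyword (default `"strain"`).
#' @param genomic_strategies library-strategy labels counted as
#'   genomic-level (whole-genome, reduced-representation, exome).
#' @param taxon_groups named character vector mapping taxon name to a group
#'   label (`"fish"`, `"plants"`, ...); unmapped taxa report `"other"`.
#' @param noneukaryote_taxa taxon names known to be outside the eukaryote
#'   scope (bacteria, archaea, viruses).
#' @return a list of class `scope_rules`.
#' @export
scope_rules <- function(
    domesticated_taxa = c("Bos taurus", "Sus scrofa", "Gallus gallus",
                          "Ovis aries", "Capra hircus", "Equus caballus",
                          "Canis lupus familiaris", "Felis catus",
                          "Oryza sativa", "Zea mays", "Triticum aestivum",
                          "Hordeum vulgare", "Glycine max", "Solanum lycopersicum",
                          "Vitis vinifera", "Malus domestica"),
    domestication_keywords = c("cultivar", "breed", "variety", "farm",
                               "farmed", "hatchery", "aquaculture",
                               "domesticated", "landrace"),
    captivity_keywords = c("captive", "captivity", "zoo", "lab", "laboratory",
                           "culture collection", "lab reared", "aquarium"),
    context_keywords = "strain",
    genomic_strategies = c("wgs", "wga", "wxs", "rad-seq", "radseq", "gbs",
                           "ddrad", "reduced representation", "exome",
                           "whole genome", "hi-c", "clone"),
    taxon_groups = default_taxon_groups(),
    noneukaryote_taxa = c("Escherichia coli", "Salmonella enterica",
                          "Bacillus subtilis", "Mycobacterium tuberculosis",
                          "Prochlorococcus marinus",
                          "Haloferax volcanii", "Influenza A virus")) {
  if (length(intersect(tolower(domestication_keywords),
                       tolower(captivity_keywords)))) {
    stop("domestication and captivity keyword sets must be disjoint")
  }
  structure(list(domesticated_taxa = domesticated_taxa,
                 domestication_keywords = domestication_keywords,
                 captivity_keywords = captivity_keywords,
                 context_keywords = context_keywords,
                 genomic_strategies = tolower(genomic_strategies),
                 taxon_groups = taxon_groups,
                 noneukaryote_taxa = noneukaryote_taxa),
            class = "scope_rules")
}

#' Default taxon-to-group mapping
#'
#' A small deterministic mapping from taxon names to coarse groups, used
#' for the taxonomic breakdown of audit summaries. Extend or replace via
#' [scope_rules()]; unmapped taxa report `"other"`.
#'
#' @return named character vector (names: taxa, values: group labels).
#' @export
default_taxon_groups <- function() {
  c("Danio rerio" = "fish", "Gasterosteus aculeatus" = "fish",
    "Salmo trutta" = "fish", "Oncorhynchus mykiss" = "fish",
    "Gadus morhua" = "fish", "Amphiprion clarkii" = "fish",
    "Peromyscus maniculatus" = "mammals", "Ursus arctos" = "mammals",
    "Microtus arvalis" = "mammals", "Bos taurus" = "mammals",
    "Sus scrofa" = "mammals", "Ovis aries" = "mammals",
    "Canis lupus familiaris" = "mammals", "Capra hircus" = "mammals",
    "Equus caballus" = "mammals", "Felis catus" = "mammals",
    "Parus major" = "birds", "Ficedula albicollis" = "birds",
    "Zonotrichia leucophrys" = "birds", "Gallus gallus" = "birds",
    "Drosophila melanogaster" = "insects", "Anopheles gambiae" = "insects",
    "Bombus terrestris" = "insects", "Aedes aegypti" = "insects",
    "Arabidopsis thaliana" = "plants", "Quercus robur" = "plants",
    "Picea abies" = "plants", "Oryza sativa" = "plants",
    "Zea mays" = "plants", "Triticum aestivum" = "plants",
    "Hordeum vulgare" = "plants", "Glycine max" = "plants",
    "Solanum lycopersicum" = "plants", "Vitis vinifera" = "plants",
    "Malus domestica" = "plants",
    "Crassostrea gigas" = "other", "Acropora millepora" = "other",
    "Octopus vulgaris" = "other")
}

match_keywords <- function(text, keywords) {
  hits <- character(0)
  for (kw in keywords) {
    pat <- paste0("\\b", gsub("([^[:alnum:] _])", "\\\\\\1", kw), "\\b")
    if (any(grepl(pat, text, ignore.case = TRUE, perl = TRUE))) {
      hits <- c(hits, kw)
    }
  }
  hits
}

#' Classify one sample as wild, domesticated, or captive
#'
#' Rule order: a taxon on the domesticated-species list forces
#' `domesticated` (species-level exclusion beats per-sample evidence);
#' otherwise any domestication keyword in the attribute keys or values
#' (word-boundary, case-insensitive) gives `domesticated`; otherwise any
#' captivity keyword gives `captive`; otherwise the sample is *putatively*
#' `wild` -- the default branch, which is exactly why filter precision must
#' be validated by subsampling. The evidence field lists every match.
#'
#' @param taxon_name the sample's taxon name.
#' @param attributes the sample's attribute tibble (columns `key`, `value`).
#' @param rules a [scope_rules()].
#' @return list with `call` (`"wild"`, `"domesticated"`, `"captive"`) and
#'   `evidence` (tibble of `rule`, `match`).
#' @export
classify_wildness <- function(taxon_name, attributes, rules = scope_rules()) {
  evidence <- tibble::tibble(rule = character(), match = character())
  if (!is.na(taxon_name) && taxon_name %in% rules$domesticated_taxa) {
    evidence <- tibble::add_row(evidence, rule = "domesticated_taxon",
                                match = taxon_name)
  }
  text <- c(attributes$key, attributes$value)
  dom_hits <- match_keywords(text, rules$domestication_keywords)
  cap_hits <- match_keywords(text, rules$captivity_keywords)
  if (length(dom_hits)) {
    evidence <- dplyr::bind_rows(evidence,
      tibble::tibble(rule = "domestication_keyword", match = dom_hits))
    ctx_hits <- match_keywords(text, rules$context_keywords)
    if (length(ctx_hits)) {
      evidence <- dplyr::bind_rows(evidence,
        tibble::tibble(rule = "domestication_context", match = ctx_hits))
    }
  }
  if (length(cap_hits)) {
    evidence <- dplyr::bind_rows(evidence,
      tibble::tibble(rule = "captivity_keyword", match = cap_hits))
  }
  call <- if (any(evidence$rule %in% c("domesticated_taxon",
                                       "domestication_keyword"))) {
    "domesticated"
  } else if (length(cap_hits)) "captive" else "wild"
  list(call = call, evidence = evidence)
}

#' Classify every sample in a corpus
#'
#' Vectorized wildness classification; attaches `corpus$wildness`, a tibble
#' with one row per sample (`call`, `evidence` as a `"rule:match"`
#' semicolon-collapsed string).
#'
#' @param corpus an `insdc_corpus`.
#' @param rules a [scope_rules()].
#' @return the corpus with a `wildness` component.
#' @export
classify_corpus_wildness <- function(corpus, rules = scope_rules()) {
  smp <- corpus$samples
  n <- nrow(smp)
  dom_taxon <- !is.na(smp$taxon_name) & smp$taxon_name %in% rules$domesticated_taxa

  # one concatenated text blob per sample, then one grepl per keyword
  blob <- rep("", n)
  if (nrow(corpus$attributes)) {
    agg <- corpus$attributes |>
      dplyr::group_by(.data$sample_accession) |>
      dplyr::summarise(text = paste(c(.data$key, .data$value), collapse = " \n "),
                       .groups = "drop")
    blob[match(agg$sample_accession, smp$sample_accession)] <- agg$text
  }
  keyword_matrix <- function(keywords) {
    hits <- matrix(FALSE, n, length(keywords))
    for (j in seq_along(keywords)) {
      pat <- paste0("\\b",
                    gsub("([^[:alnum:] _])", "\\\\\\1", keywords[j]),
                    "\\b")
      hits[, j] <- grepl(pat, blob, ignore.case = TRUE, perl = TRUE)
    }
    colnames(hits) <- keywords
    hits
  }
  dom_m <- keyword_matrix(rules$domestication_keywords)
  cap_m <- keyword_matrix(rules$captivity_keywords)
  dom_kw <- rowSums(dom_m) > 0
  cap_kw <- rowSums(cap_m) > 0
  call <- unname(ifelse(dom_taxon | dom_kw, "domesticated",
                        ifelse(cap_kw, "captive", "wild")))
  collapse_hits <- function(m, rule) {
    apply(m, 1, function(r) {
      if (!any(r)) "" else
        paste(paste0(rule, ":", colnames(m)[r]), collapse = ";")
    })
  }
  ev <- paste(ifelse(dom_taxon, paste0("domesticated_taxon:", smp$taxon_name), ""),
              collapse_hits(dom_m, "domestication_keyword"),
              collapse_hits(cap_m, "captivity_keyword"), sep = ";")
  ev <- gsub("^;+|;+$", "", gsub(";{2,}", ";", ev))
  corpus$wildness <- tibble::tibble(
    sample_accession = smp$sample_accession, call = call, evidence = ev)
  corpus
}

#' Is a record in genomic-level eukaryote scope?
#'
#' A record is in scope when its taxon is (as far as the rule set knows) a
#' eukaryote and its library strategy is a genomic-level one (whole-genome,
#' reduced-representation, exome). A missing strategy annotation yields an
#' `NA` scope with reason `"missing_strategy"` -- counted separately, never
#' silently excluded.
#'
#' @param taxon_name the record's taxon name.
#' @param library_strategy the record's library-strategy label (or `NA`).
#' @param rules a [scope_rules()].
#' @return list with `in_scope` (`TRUE`/`FALSE`/`NA`) and `reason`.
#' @export
in_genomic_scope <- function(taxon_name, library_strategy,
                             rules = scope_rules()) {
  if (!is.na(taxon_name) && taxon_name %in% rules$noneukaryote_taxa) {
    return(list(in_scope = FALSE, reason = "taxon"))
  }
  if (is.na(library_strategy) || !nzchar(trimws(library_strategy))) {
    return(list(in_scope = NA, reason = "missing_strategy"))
  }
  if (tolower(trimws(library_strategy)) %in% rules$genomic_strategies) {
    list(in_scope = TRUE, reason = NA_character_)
  } else {
    list(in_scope = FALSE, reason = "strategy")
  }
}

#' Map a taxon to its audit group
#'
#' Deterministic lookup in the configured group table; unmapped taxa
#' report `"other"`.
#'
#' @param taxon_name character vector of taxon names.
#' @param rules a [scope_rules()].
#' @return character vector of group labels.
#' @export
assign_taxon_group <- function(taxon_name, rules = scope_rules()) {
  g <- unname(rules$taxon_groups[taxon_name])
  g[is.na(g)] <- "other"
  g
}
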