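Package: insdcmeta
Title: Audit Spatiotemporal Metadata Completeness in Genomic Sequence Archives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the completeness of spatiotemporal metadata
    (latitude/longitude, collection year, place and country names) attached to
    sample records in INSDC-style sequence archives. Parses the free-text
    attribute dialects found in BioSample records, recovers values misfiled
    under non-canonical keys, classifies samples as wild, domesticated or
    captive with configurable keyword rules, rolls sample-level status up to
    datasets (BioProjects), validates the wild filter by random subsampling
    with bootstrap confidence intervals, merges externally recovered metadata,
    and estimates the monetary cost of metadata loss. Includes a synthetic
    corpus generator with per-record ground truth so the whole pipeline can be
    exercised and verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
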