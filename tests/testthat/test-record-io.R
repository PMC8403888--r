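biosample_xml_text <- '<?xml version="1.0"?>
<BioSampleSet>
  <BioSample accession="SAMX0001" submission_date="2015-03-02">
    <Description><Organism taxonomy_name="Danio rerio" taxonomy_id="7955"/></Description>
    <Attributes>
      <Attribute attribute_name="Lat Lon" harmonized_name="lat_lon">12.5 N 45.5 E</Attribute>
      <Attribute attribute_name="lat_lon">13.5 N 46.5 E</Attribute>
      <Attribute attribute_name="collection_date">2010-05-01</Attribute>
    </Attributes>
    <Links><Link type="entrez" target="bioproject" label="PRJX1">PRJX1</Link></Links>
  </BioSample>
  <BioSample accession="SAMX0002">
    <Description><Organism taxonomy_name="Parus major" taxonomy_id="9157"/></Description>
    <Links><Link type="entrez" target="bioproject" label="PRJX1">PRJX1</Link></Links>
  </BioSample>
</BioSampleSet>'

test_that("BioSample XML maps structurally onto a corpus", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(biosample_xml_text, path)
  corpus <- read_biosample_xml(path)
  expect_equal(nrow(corpus$samples), 2)
  ds <- corpus_datasets(corpus)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$dataset_accession, "PRJX1")
  expect_equal(ds$n_samples, 2)
  expect_equal(corpus$samples$taxon_name[corpus$samples$sample_accession ==
                                           "SAMX0001"], "Danio rerio")
  expect_equal(corpus$samples$deposition_year[1], 2015L)
  # duplicate lat_lon keys are both retained, in order
  a <- sample_attributes(corpus, "SAMX0001")
  expect_equal(sum(a$key == "lat_lon"), 2)
  expect_equal(a$value[a$key == "lat_lon"], c("12.5 N 45.5 E", "13.5 N 46.5 E"))
  expect_equal(corpus$n_skipped, 0L)
})

test_that("empty and malformed XML are handled", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<BioSampleSet></BioSampleSet>", path)
  corpus <- read_biosample_xml(path)
  expect_equal(nrow(corpus$samples), 0)
  expect_equal(nrow(corpus_datasets(corpus)), 0)

  writeLines("<BioSampleSet><oops", path)
  expect_error(read_biosample_xml(path), "malformed")
})

test_that("records without accession are skipped and tallied", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<BioSampleSet>
    <BioSample accession="SAMX1"><Links><Link target="bioproject" label="P1">P1</Link></Links></BioSample>
    <BioSample><Description/></BioSample>
  </BioSampleSet>', path)
  expect_warning(corpus <- read_biosample_xml(path), "skipped")
  expect_equal(nrow(corpus$samples), 1)
  expect_equal(corpus$n_skipped, 1L)
  # skip tally + parsed count = total input record count
  expect_equal(nrow(corpus$samples) + corpus$n_skipped, 2)
})

test_that("samples without a dataset link get an unlinked singleton", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<BioSampleSet><BioSample accession="SAMX9"/></BioSampleSet>', path)
  corpus <- read_biosample_xml(path)
  expect_equal(nrow(corpus$samples), 1)
  expect_true(all(corpus$memberships$unlinked))
})

write_flat_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(paste(c("sample_accession", "dataset_accession", "taxon_name",
                       "taxon_id", "deposition_year", "attr_key",
                       "attr_value"), collapse = "\t"), lines), path)
  path
}

test_that("flat table rows group into samples and datasets", {
  path <- write_flat_text(c(
    "S1\tP1\tDanio rerio\t7955\t2018\tlat_lon\t1.0 N 2.0 E",
    "S1\tP1\tDanio rerio\t7955\t2018\tcollection_date\t2010",
    "S1\tP1\tDanio rerio\t7955\t2018\tgeo_loc_name\tFrance",
    "S2\tP1\tParus major\t\t2019\tlat_lon\tmissing",
    "S3\tP2\tParus major\t\t2019\t\t"))
  corpus <- read_flat_table(path)
  expect_equal(nrow(corpus$samples), 3)
  expect_equal(nrow(corpus_datasets(corpus)), 2)
  expect_equal(nrow(sample_attributes(corpus, "S1")), 3)
  # empty attr_value retained; empty attr_key means "no attribute"
  expect_equal(nrow(sample_attributes(corpus, "S3")), 0)
})

test_that("flat table schema violations are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_accession\tattr_key\nS1\tx", path)
  expect_error(read_flat_table(path), "dataset_accession")

  path2 <- write_flat_text(c(
    "S1\tP1\tDanio rerio\t\t2018\tnote\ta",
    "S1\tP1\tParus major\t\t2018\tnote\tb"))
  expect_error(read_flat_table(path2), "S1")
})

test_that("an empty flat table yields an empty corpus", {
  path <- write_flat_text(character(0))
  corpus <- read_flat_table(path)
  expect_equal(nrow(corpus$samples), 0)
  expect_equal(nrow(corpus_datasets(corpus)), 0)
})

test_that("flat-table round trip preserves the corpus", {
  gen <- generate_corpus(synthetic_config(n_datasets = 15, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flat_table(gen$corpus, path)
  back <- read_flat_table(path)
  expect_equal(back$samples[order(back$samples$sample_accession), ],
               gen$corpus$samples[order(gen$corpus$samples$sample_accession), ])
  expect_equal(dplyr::arrange(back$attributes, sample_accession, ord),
               dplyr::arrange(gen$corpus$attributes, sample_accession, ord))
  expect_equal(dplyr::arrange(back$memberships, sample_accession),
               dplyr::arrange(gen$corpus$memberships, sample_accession))
})

test_that("XML and flat serializations parse to the same corpus", {
  gen <- generate_corpus(synthetic_config(n_datasets = 8, seed = 11))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  xml <- withr::local_tempfile(fileext = ".xml")
  write_flat_table(gen$corpus, tsv)
  write_biosample_xml(gen$corpus, xml)
  a <- read_flat_table(tsv)
  b <- read_biosample_xml(xml)
  ord <- function(cc) list(
    s = cc$samples[order(cc$samples$sample_accession),
                   c("sample_accession", "taxon_name", "deposition_year")],
    a = dplyr::arrange(cc$attributes, sample_accession, ord)[,
                       c("sample_accession", "key", "value", "ord")],
    m = dplyr::arrange(cc$memberships, sample_accession))
  expect_equal(ord(a), ord(b))
})

test_that("deposition years outside the archive era are rejected", {
  expect_error(
    make_corpus(list(list(acc = "S1", year = 1950L))),
    "deposition_year")
})

test_that("audit tables are deterministic and conserve counts", {
  corpus <- fixture_status_corpus()
  s <- summarize_corpus(corpus)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_audit_tables(s, d1, growth = summarize_growth(corpus))
  p2 <- write_audit_tables(s, d2, growth = summarize_growth(corpus))
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(sum(unlist(rep$totals[c("n_wild_samples",
                                       "n_domesticated_samples",
                                       "n_captive_samples")])),
               rep$totals$n_samples)
  props <- unlist(rep$proportions)
  expect_true(all(props >= 0 & props <= 1, na.rm = TRUE))

  # empty corpus: header-only tables
  empty <- summarize_corpus(make_empty_corpus())
  d3 <- withr::local_tempdir()
  p3 <- write_audit_tables(empty, d3)
  per_sample <- readLines(p3[1])
  expect_length(per_sample, 1)
})
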