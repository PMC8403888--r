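test_that("status cells follow the coordinate/year booleans", {
  corpus <- parse_corpus(fixture_status_corpus())
  st <- classify_sample_status(corpus$parsed)
  expect_equal(sum(st$cell == "both"), 3)
  expect_equal(sum(st$cell == "coords_only"), 2)
  expect_equal(sum(st$cell == "year_only"), 4)
  expect_equal(sum(st$cell == "neither"), 1)
  expect_true(all(st$has_coordinates == (st$cell %in% c("both", "coords_only"))))
})

test_that("a (0,0) coordinate is discounted under the default policy", {
  attrs <- make_attrs(lat_lon = "0.0, 0.0", collection_date = "2010")
  corpus <- make_corpus(list(list(acc = "S1", attrs = attrs)))
  st <- classify_sample_status(parse_corpus(corpus)$parsed)
  expect_false(st$has_coordinates)
  expect_equal(st$cell, "year_only")
  expect_equal(st$location_tier, "none")
  st2 <- classify_sample_status(parse_corpus(corpus)$parsed,
                                audit_policy(count_zero_zero = TRUE))
  expect_true(st2$has_coordinates)
  expect_equal(st2$cell, "both")
})

test_that("dataset rollup rules have the stated semantics", {
  full <- tibble::tibble(has_coordinates = rep(TRUE, 5),
                         has_year = rep(TRUE, 5), cell = rep("both", 5))
  for (rule in c("all", "any", "proportion")) {
    r <- rollup_dataset(full, rule)
    expect_true(r$dataset_has_both, info = rule)
  }
  partial <- tibble::tibble(has_coordinates = c(rep(TRUE, 4), FALSE),
                            has_year = rep(FALSE, 5),
                            cell = c(rep("coords_only", 4), "neither"))
  expect_false(rollup_dataset(partial, "all")$dataset_has_coords)
  expect_true(rollup_dataset(partial, "any")$dataset_has_coords)
  expect_true(rollup_dataset(partial, "proportion", p = 0.5)$dataset_has_coords)
  expect_false(rollup_dataset(partial, "proportion", p = 0.9)$dataset_has_coords)
  expect_error(rollup_dataset(partial[0, ]), "no member samples")
})

test_that("rollup rules are monotone: any >= proportion >= all, field-wise", {
  gen <- generate_corpus(synthetic_config(n_datasets = 20, seed = 3))
  corpus <- classify_corpus_wildness(parse_corpus(gen$corpus))
  d_all <- rollup_datasets(corpus, rule = "all")
  d_any <- rollup_datasets(corpus, rule = "any")
  d_prp <- rollup_datasets(corpus, rule = "proportion", p = 0.5)
  for (f in c("dataset_has_coords", "dataset_has_year", "dataset_has_both")) {
    expect_gte(mean(d_any[[f]]), mean(d_prp[[f]]))
    expect_gte(mean(d_prp[[f]]), mean(d_all[[f]]))
  }
  # independent brute-force oracle for the same booleans
  st <- classify_sample_status(corpus$parsed)
  st$ds <- corpus$memberships$dataset_accession[
    match(st$sample_accession, corpus$memberships$sample_accession)]
  for (ds in unique(st$ds)) {
    v <- st$has_coordinates[st$ds == ds]
    expect_equal(d_all$dataset_has_coords[d_all$dataset_accession == ds],
                 all(v))
    expect_equal(d_any$dataset_has_coords[d_any$dataset_accession == ds],
                 any(v))
    expect_equal(d_prp$dataset_has_coords[d_prp$dataset_accession == ds],
                 mean(v) >= 0.5)
  }
})

test_that("priority selection uses the strict more-than-four rule", {
  corpus <- fixture_wildness_corpus(list(
    PRJA = c(wild = 4, dom = 0),
    PRJB = c(wild = 5, dom = 0),
    PRJC = c(wild = 3, dom = 7),
    PRJD = c(wild = 12, dom = 1)))
  sel <- select_priority_datasets(corpus)
  expect_equal(sel$dataset_accession, c("PRJB", "PRJD"))
  expect_true(all(sel$n_wild >= 5))
})

test_that("summary proportions match a hand-counted fixture", {
  s <- summarize_corpus(fixture_status_corpus())
  p <- s$proportions
  expect_equal(p$sample_coords, 0.5)
  expect_equal(p$sample_year, 0.7)
  expect_equal(p$sample_both, 0.3)
  expect_equal(s$cells$proportion, c(0.3, 0.2, 0.4, 0.1))
  expect_lte(p$sample_both, min(p$sample_coords, p$sample_year))
  expect_equal(sum(s$cells$n), s$totals$n_samples)
})

test_that("an empty corpus reports undefined proportions, not zeros", {
  s <- summarize_corpus(make_empty_corpus())
  expect_equal(s$totals$n_samples, 0)
  expect_true(is.na(s$proportions$sample_coords))
  expect_true(is.na(s$proportions$sample_both))
})

test_that("lost-investment arithmetic and guards", {
  fake_summary <- function(n_missing) {
    structure(list(totals = list(n_missing_both = n_missing,
                                 n_missing_either = n_missing),
                   policy = audit_policy()), class = "audit_summary")
  }
  expect_equal(estimate_lost_investment(fake_summary(100))$amount, 5000)
  expect_equal(estimate_lost_investment(fake_summary(0))$amount, 0)
  expect_equal(estimate_lost_investment(fake_summary(281716))$amount,
               14085800)
  expect_error(estimate_lost_investment(fake_summary(10),
                                        cost_per_individual = -1),
               "non-negative")
  # and through the real pipeline: the fixture has 7 samples outside "both"
  s <- summarize_corpus(fixture_status_corpus())
  li <- estimate_lost_investment(s)
  expect_equal(li$amount, 7 * 50)
  expect_equal(estimate_lost_investment(s, basis = "neither")$amount, 1 * 50)
})

test_that("growth accumulates by deposition year with an unknown bin", {
  mk <- function(i, yr) list(acc = sprintf("SG%02d", i), year = yr,
                             attrs = make_attrs(collection_date = "2010"))
  corpus <- make_corpus(list(mk(1, 2018L), mk(2, 2018L), mk(3, 2019L),
                             mk(4, 2019L), mk(5, 2019L), mk(6, NA)))
  g <- summarize_growth(corpus)
  tot <- g |> dplyr::group_by(deposition_year) |>
    dplyr::summarise(cum = sum(cumulative))
  expect_equal(tot$cum, c(2, 5))
  unknown <- attr(g, "unknown")
  expect_equal(sum(unknown$n), 1)
  for (cl in unique(g$cell)) {
    expect_true(!is.unsorted(g$cumulative[g$cell == cl]))
  }
})

test_that("augmentation fills only empty slots and logs conflicts", {
  corpus <- parse_corpus(fixture_status_corpus())
  aug <- tibble::tibble(
    sample_accession = c("SAMT06", "SAMT01"),
    dataset_accession = NA_character_,
    latitude = c(5.5, 99.9), longitude = c(6.6, 8.8),
    collection_year = NA_integer_,
    place = NA_character_, country = NA_character_,
    source_citation = "doi:x")
  # SAMT01 already has archive coordinates: kept, conflict logged
  aug$latitude[2] <- 50.0
  out <- apply_augmentation(corpus, aug)
  st <- classify_sample_status(out$parsed)
  expect_true(st$has_coordinates[st$sample_accession == "SAMT06"])
  expect_equal(out$parsed$coord_origin[out$parsed$sample_accession == "SAMT06"],
               "augmentation")
  expect_equal(out$parsed$latitude[out$parsed$sample_accession == "SAMT01"],
               10.1)
  expect_equal(nrow(out$augmentation_log$conflicts), 1)

  # identity on the empty table
  out2 <- apply_augmentation(corpus, aug[0, ])
  expect_equal(out2$parsed, corpus$parsed)

  # unknown accessions error; invalid values are rejected with a reason
  bad <- aug; bad$sample_accession[1] <- "NOPE"
  expect_error(apply_augmentation(corpus, bad), "NOPE")
  inv <- aug[1, ]; inv$latitude <- 123
  out3 <- apply_augmentation(corpus, inv)
  expect_equal(out3$augmentation_log$rejected$reason, "invalid_coordinate")
})

test_that("dataset-level augmentation rows reach every member sample", {
  corpus <- parse_corpus(fixture_status_corpus())
  aug <- tibble::tibble(sample_accession = NA_character_,
                        dataset_accession = "PRJT000001",
                        latitude = 1.5, longitude = 2.5,
                        collection_year = 2001L,
                        place = NA_character_, country = "France",
                        source_citation = "doi:y")
  out <- apply_augmentation(corpus, aug)
  st <- classify_sample_status(out$parsed)
  expect_true(all(st$has_coordinates))
  expect_true(all(st$has_year))
  # archive-derived values were never overwritten
  expect_equal(out$parsed$year[out$parsed$sample_accession == "SAMT01"], 2010L)
})

test_that("augmentation never decreases any coverage proportion", {
  gen <- generate_corpus(synthetic_config(n_datasets = 30, seed = 41))
  corpus <- classify_corpus_wildness(parse_corpus(gen$corpus))
  before <- summarize_corpus(corpus)
  missing <- corpus$parsed$sample_accession[is.na(corpus$parsed$latitude)]
  aug <- tibble::tibble(sample_accession = head(missing, 20),
                        dataset_accession = NA_character_,
                        latitude = 10, longitude = 20,
                        collection_year = 2005L,
                        place = "Deep Cove", country = "Canada",
                        source_citation = "doi:z")
  after <- summarize_corpus(apply_augmentation(corpus, aug))
  for (f in c("sample_coords", "sample_year", "sample_both",
              "sample_some_location_and_year", "sample_country_or_better")) {
    expect_gte(after$proportions[[f]], before$proportions[[f]])
  }
})
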