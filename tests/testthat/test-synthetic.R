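test_that("config validation rejects infeasible joint laws and mixtures", {
  expect_error(synthetic_config(p_coords = 0.2, p_year = 0.2,
                                p_both_excess = 0.3), "infeasible")
  expect_error(synthetic_config(p_coords = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(dialect_mixture = c(hemisphere_letters = 0.5,
                                                    signed_decimal = 0.2,
                                                    dms = 0.1,
                                                    split_fields = 0.1)),
               "sum to 1")
})

test_that("saturated presence yields the both cell everywhere", {
  cfg <- synthetic_config(n_datasets = 10, p_coords = 1, p_year = 1,
                          p_both_excess = 0, p_placeholder = 0,
                          p_misfiled = 0, seed = 7)
  gen <- generate_corpus(cfg)
  st <- classify_sample_status(parse_corpus(gen$corpus)$parsed)
  expect_true(all(st$cell == "both"))
})

test_that("identical seeds give byte-identical corpora", {
  cfg <- synthetic_config(n_datasets = 12, seed = 101)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_flat_table(g1$corpus, p1)
  write_flat_table(g2$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(g1$truth, g2$truth)
})

test_that("rendering is the inverse of parsing, per dialect", {
  r <- render_coordinate(-36.5, 174.7, "hemisphere_letters")
  expect_equal(r$text, "36.500000 S 174.700000 E")
  expect_equal(render_collection_date(1999L, "year"), "1999")
  expect_equal(render_collection_date(2008L, "range", 2010L), "2008/2010")
  expect_equal(render_collection_date(2009L, "month", month = 7,
                                      style = "name"), "Jul-2009")
  expect_error(render_coordinate(1, 2, "polar"), "unknown dialect")
  expect_error(render_collection_date(2000, "century"), "unknown precision")

  set.seed(55)
  lat <- runif(50, -89, 89); lon <- runif(50, -179, 179)
  for (d in c("hemisphere_letters", "signed_decimal", "dms")) {
    p <- parse_lat_lon(render_coordinate(lat, lon, d)$text)
    tol <- if (d == "dms") 1e-4 else 1e-6
    expect_true(all(abs(p$latitude - lat) < tol), info = d)
  }
})

test_that("substreams isolate concerns: masking toggles leave structure alone", {
  base <- synthetic_config(n_datasets = 25, p_misfiled = 0, seed = 61)
  more <- synthetic_config(n_datasets = 25, p_misfiled = 0.4, seed = 61)
  g1 <- generate_corpus(base)
  g2 <- generate_corpus(more)
  # same datasets, sizes, wildness, and the same presence truth
  expect_identical(g1$dataset_truth, g2$dataset_truth)
  expect_identical(g1$truth$has_coords, g2$truth$has_coords)
  expect_identical(g1$truth$true_latitude, g2$truth$true_latitude)
  expect_identical(g1$truth$coord_masked, g2$truth$coord_masked)
  # only misfiling differs
  expect_equal(sum(g1$truth$coord_misfiled), 0)
  expect_gt(sum(g2$truth$coord_misfiled), 0)
})

test_that("parsing recovers the generator's presence flags exactly", {
  for (seed in c(5, 19, 83)) {
    cfg <- synthetic_config(n_datasets = 25, p_placeholder = 0,
                            p_misfiled = 0, seed = seed)
    gen <- generate_corpus(cfg)
    st <- classify_sample_status(parse_corpus(gen$corpus)$parsed)
    expect_identical(st$has_coordinates, gen$truth$has_coords)
    expect_identical(st$has_year, gen$truth$has_year)
    # and the values themselves, within dialect tolerance
    i <- st$has_coordinates
    expect_true(all(abs(parse_corpus(gen$corpus)$parsed$latitude[i] -
                          gen$truth$true_latitude[i]) < 1e-4))
  }
})

test_that("misfiled values vanish without scanning and return with it", {
  cfg <- synthetic_config(n_datasets = 30, p_placeholder = 0,
                          p_misfiled = 0.25, seed = 37)
  gen <- generate_corpus(cfg)
  on <- classify_sample_status(
    parse_corpus(gen$corpus, parser_config(scan_misfiled = TRUE))$parsed)
  off <- classify_sample_status(
    parse_corpus(gen$corpus, parser_config(scan_misfiled = FALSE))$parsed)
  expect_identical(on$has_coordinates, gen$truth$has_coords)
  mis <- gen$truth$coord_misfiled
  expect_true(all(!off$has_coordinates[mis]))
  expect_identical(off$has_coordinates, gen$truth$has_coords & !mis)
})

test_that("empirical joint cells converge to the configured law", {
  cfg <- synthetic_config(n_datasets = 600, size_mu = 10,
                          p_coords = 0.3, p_year = 0.5, p_both_excess = 0.1,
                          p_placeholder = 0, seed = 71)
  gen <- generate_corpus(cfg)
  n <- nrow(gen$truth)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(gen$truth$has_coords) - 0.3), 3 * se(0.3))
  expect_lt(abs(mean(gen$truth$has_year) - 0.5), 3 * se(0.5))
  expect_lt(abs(mean(gen$truth$has_coords & gen$truth$has_year) - 0.25),
            3 * se(0.25))
})

test_that("ground truth is consistent with emitted attribute text", {
  gen <- generate_corpus(synthetic_config(n_datasets = 20, seed = 47))
  # every sample with observable coordinates has a parseable attribute
  corpus <- parse_corpus(gen$corpus)
  st <- classify_sample_status(corpus$parsed)
  expect_identical(st$has_coordinates, gen$truth$obs_coords)
  expect_identical(st$has_year, gen$truth$obs_year)
  expect_equal(nrow(gen$truth), nrow(gen$corpus$samples))
})
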