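test_that("combined coordinate dialects parse with correct sign and value", {
  cases <- list(
    list("36.21 N 121.77 W", 36.21, -121.77, "hemisphere_letters"),
    list("36.21 S, 121.77 E", -36.21, 121.77, "hemisphere_letters"),
    list("N 40.7 W 74.0", 40.7, -74.0, "hemisphere_letters"),
    list("-36.5, 174.7", -36.5, 174.7, "signed_decimal"),
    list("12.5 45.25", 12.5, 45.25, "signed_decimal"),
    list("36°12'36\" S 121°46'48\" E", -36.21, 121.78, "dms"),
    list("10°30'0\" N, 20°15'0\" W", 10.5, -20.25, "dms"))
  for (cs in cases) {
    r <- parse_lat_lon(cs[[1]])
    expect_equal(r$latitude, cs[[2]], tolerance = 1e-6, info = cs[[1]])
    expect_equal(r$longitude, cs[[3]], tolerance = 1e-6, info = cs[[1]])
    expect_equal(r$dialect, cs[[4]], info = cs[[1]])
    expect_true(is.na(r$reason))
  }
})

test_that("coordinate failures carry exactly one rejection category", {
  r <- parse_lat_lon(c("not collected", "", "NA", "Unknown"))
  expect_true(all(r$reason == "placeholder"))
  r <- parse_lat_lon(c("91.0 N 10.0 E", "45.0 N 181.0 E", "95, 10"))
  expect_true(all(r$reason == "out_of_range"))
  r <- parse_lat_lon(c("somewhere nice", "36.5", "x, y"))
  expect_true(all(r$reason == "unparseable"))
  expect_true(all(is.na(r$latitude)))
})

test_that("(0,0) parses as valid but is flagged", {
  r <- parse_lat_lon("0.0, 0.0")
  expect_equal(r$latitude, 0)
  expect_true(r$zero_zero)
  r2 <- parse_lat_lon("0.0, 10.0")
  expect_false(r2$zero_zero)
})

test_that("split latitude/longitude fields parse as a pair", {
  r <- parse_split_coordinates("-36.5", "174.7")
  expect_equal(c(r$latitude, r$longitude), c(-36.5, 174.7))
  expect_equal(r$dialect, "split_fields")
  r <- parse_split_coordinates("36.5 S", "174.7 E")
  expect_equal(c(r$latitude, r$longitude), c(-36.5, 174.7))
  r <- parse_split_coordinates("36.5", "")
  expect_true(is.na(r$latitude))
  r <- parse_split_coordinates("95", "10")
  expect_equal(r$reason, "out_of_range")
})

test_that("parser totality: arbitrary text never raises", {
  g <- garble_strings(300)
  r <- parse_lat_lon(g)
  expect_equal(nrow(r), 300)
  failed <- is.na(r$latitude)
  expect_true(all(r$reason[failed] %in%
                    c("placeholder", "unparseable", "out_of_range")))
  expect_true(all(is.na(r$reason[!failed])))
  d <- parse_collection_date(g)
  failed <- is.na(d$year)
  expect_true(all(d$reason[failed] %in%
                    c("placeholder", "unparseable", "out_of_range")))
})

test_that("rendered coordinates round-trip through the parsers", {
  set.seed(31)
  n <- 200
  lat <- round(runif(n, -89.9, 89.9), 4)
  lon <- round(runif(n, -179.9, 179.9), 4)
  for (dia in c("hemisphere_letters", "signed_decimal", "dms")) {
    txt <- render_coordinate(lat, lon, dia)$text
    r <- parse_lat_lon(txt)
    tol <- if (dia == "dms") 1e-4 else 1e-6
    expect_true(all(abs(r$latitude - lat) < tol), info = dia)
    expect_true(all(abs(r$longitude - lon) < tol), info = dia)
    expect_true(all(r$dialect == dia), info = dia)
  }
  sp <- render_coordinate(lat, lon, "split_fields")
  r <- parse_split_coordinates(sp$lat_text, sp$lon_text)
  expect_true(all(abs(r$latitude - lat) < 1e-6))
  expect_true(all(abs(r$longitude - lon) < 1e-6))
})

test_that("the same location agrees across dialects within DMS granularity", {
  set.seed(32)
  lat <- round(runif(50, -89, 89), 4)
  lon <- round(runif(50, -179, 179), 4)
  parsed <- lapply(c("hemisphere_letters", "signed_decimal", "dms"),
                   function(d) parse_lat_lon(render_coordinate(lat, lon, d)$text))
  for (i in 2:3) {
    expect_true(all(abs(parsed[[1]]$latitude - parsed[[i]]$latitude) < 1e-4))
    expect_true(all(abs(parsed[[1]]$longitude - parsed[[i]]$longitude) < 1e-4))
  }
})

test_that("date formats map to the correct year and precision", {
  cases <- list(
    list("2008-07-15", 2008L, "day", NA_integer_),
    list("2008-07", 2008L, "month", NA_integer_),
    list("2008", 2008L, "year", NA_integer_),
    list("Jul-2009", 2009L, "month", NA_integer_),
    list("15-Jul-1999", 1999L, "day", NA_integer_),
    list("03 March 2011", 2011L, "day", NA_integer_),
    list("2008/2010", 2008L, "range", 2010L),
    list("2010-2008", 2008L, "range", 2010L),
    list("sampled in 2012 from reef", 2012L, "year", NA_integer_))
  for (cs in cases) {
    r <- parse_collection_date(cs[[1]])
    expect_equal(r$year, cs[[2]], info = cs[[1]])
    expect_equal(r$precision, cs[[3]], info = cs[[1]])
    expect_equal(r$range_end_year, cs[[4]], info = cs[[1]])
  }
})

test_that("date plausibility window and placeholders are enforced", {
  r <- parse_collection_date(c("0", "1750", "3025"))
  expect_true(all(is.na(r$year)))
  expect_true(all(r$reason == "out_of_range"))
  r <- parse_collection_date(c("missing", "not applicable"))
  expect_true(all(r$reason == "placeholder"))
  r <- parse_collection_date("soon")
  expect_equal(r$reason, "unparseable")
})

test_that("geographic names split into country and place by tier", {
  attrs <- make_attrs(geo_loc_name = "USA: Wisconsin, Lake Mendota")
  loc <- extract_location(attrs, has_coordinate = FALSE)
  expect_equal(loc$tier, "place_name")
  expect_equal(loc$country, "USA")
  expect_equal(loc$place, "Lake Mendota")

  loc <- extract_location(make_attrs(geo_loc_name = "France"), FALSE)
  expect_equal(loc$tier, "country")
  expect_equal(loc$country, "France")
  expect_true(is.na(loc$place))

  loc <- extract_location(make_attrs(note = "x"), TRUE)
  expect_equal(loc$tier, "coordinates")
  expect_true(is.na(loc$country))

  # synonyms map to the canonical name; country known even when tier finer
  loc <- extract_location(make_attrs(geo_loc_name = "Brasil: Rio Negro"), FALSE)
  expect_equal(loc$country, "Brazil")
  expect_equal(loc$tier, "place_name")

  loc <- extract_location(make_attrs(geo_loc_name = "not collected"), FALSE)
  expect_equal(loc$tier, "none")
})

test_that("misfiled values are recovered from non-canonical keys only", {
  rec <- scan_misfiled(make_attrs(isolation_source = "41.40 N 2.17 E"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$kind, "coordinate")
  expect_equal(rec$latitude, 41.4)

  rec <- scan_misfiled(make_attrs(lat_lon = "41.40 N 2.17 E"))
  expect_equal(nrow(rec), 0)

  rec <- scan_misfiled(make_attrs(description = "sampled in 2012 from reef"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$kind, "temporal")
  expect_equal(rec$year, 2012L)
})

test_that("canonical slots win and misfiled recoveries are promoted", {
  pm <- parse_sample(make_attrs(lat_lon = "36.21 N 121.77 W",
                                collection_date = "2008-07-15"))
  expect_equal(pm$coordinate$origin, "archive")
  expect_equal(pm$temporal$origin, "archive")
  expect_equal(pm$coordinate$latitude, 36.21)
  expect_equal(pm$temporal$collection_year, 2008L)

  pm <- parse_sample(make_attrs(lat_lon = "missing",
                                description = "site at 40.7 N 74.0 W"))
  # free text around a coordinate is not a canonical parse...
  expect_null(pm$coordinate)
  pm <- parse_sample(make_attrs(lat_lon = "missing",
                                description = "40.7 N 74.0 W"))
  expect_equal(pm$coordinate$origin, "misfiled")
  expect_equal(pm$coordinate$latitude, 40.7)
  expect_equal(pm$coordinate$source_key, "description")

  pm <- parse_sample(make_attrs(note = "nothing to see"))
  expect_null(pm$coordinate)
  expect_null(pm$temporal)
  expect_equal(pm$location$tier, "none")
})

test_that("split fields feed the coordinate slot when lat_lon is absent", {
  pm <- parse_sample(make_attrs(latitude = "36.5 S", longitude = "174.7 E"))
  expect_equal(pm$coordinate$dialect, "split_fields")
  expect_equal(pm$coordinate$latitude, -36.5)
})

test_that("misfiled scanning never decreases coordinate or year counts", {
  gen <- generate_corpus(synthetic_config(n_datasets = 40, p_misfiled = 0.3,
                                          seed = 17))
  on_cfg <- parser_config(scan_misfiled = TRUE)
  off_cfg <- parser_config(scan_misfiled = FALSE)
  on <- classify_sample_status(parse_corpus(gen$corpus, on_cfg)$parsed)
  off <- classify_sample_status(parse_corpus(gen$corpus, off_cfg)$parsed)
  expect_gte(sum(on$has_coordinates), sum(off$has_coordinates))
  expect_gte(sum(on$has_year), sum(off$has_year))
  # recovered counts equal the generator's misfiled counts
  expect_equal(sum(on$has_coordinates) - sum(off$has_coordinates),
               sum(gen$truth$coord_misfiled))
  expect_equal(sum(on$has_year) - sum(off$has_year),
               sum(gen$truth$year_misfiled))
})

test_that("a sample's tier equals the best evidence available", {
  tiers <- c(coordinates = 3, place_name = 2, country = 1, none = 0)
  pm_c <- parse_sample(make_attrs(lat_lon = "1 N 2 E",
                                  geo_loc_name = "France: Alsace"))
  pm_p <- parse_sample(make_attrs(geo_loc_name = "France: Alsace"))
  pm_n <- parse_sample(make_attrs(geo_loc_name = "France"))
  pm_0 <- parse_sample(make_attrs(note = "x"))
  expect_equal(pm_c$location$tier, "coordinates")
  expect_equal(pm_p$location$tier, "place_name")
  expect_equal(pm_n$location$tier, "country")
  expect_equal(pm_0$location$tier, "none")
  expect_true(tiers[pm_c$location$tier] > tiers[pm_p$location$tier])
  expect_true(tiers[pm_p$location$tier] > tiers[pm_n$location$tier])
  expect_true(tiers[pm_n$location$tier] > tiers[pm_0$location$tier])
})
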