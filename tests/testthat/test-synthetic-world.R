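test_that("identical spec and seed regenerate bit-identical tables", {
  spec <- tiny_world_spec(seed = 7)
  w1 <- generate_world(spec)
  w2 <- generate_world(spec)
  expect_identical(w1, w2)
  # a different seed changes the draws
  w3 <- generate_world(tiny_world_spec(seed = 8))
  expect_false(identical(w1$training$ph, w3$training$ph))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_world(tiny_world_spec(seed = 3)))
  expect_identical(before, .Random.seed)
})

test_that("degenerate generator: no noise, no cycle, no trend gives the bare spatial field", {
  spec <- silent_world_spec()
  w <- generate_world(spec)
  expected <- spec$ph_baseline +
    spec$ph_lat_coef * (w$training$latitude - spec$lat0) +
    spec$ph_depth_coef * w$training$depth_m
  expect_equal(w$training$ph, expected, tolerance = 1e-12)
})

test_that("planted labels decompose into the generator terms when noise is zero", {
  spec <- tiny_world_spec(seed = 5, noise_sd = zero_noise_sd())
  w <- generate_world(spec)
  truth <- true_labels(w$truth, w$training)
  expect_equal(w$training$ph[!is.na(w$training$ph)],
               truth$ph[!is.na(w$training$ph)], tolerance = 1e-12)
  expect_equal(w$training$ta_umol_kg[!is.na(w$training$ta_umol_kg)],
               truth$ta[!is.na(w$training$ta_umol_kg)], tolerance = 1e-12)
})

test_that("prediction table rows equal stations x bins x weeks from an independent calendar count", {
  spec <- tiny_world_spec(seed = 2)
  w <- generate_world(spec)
  # brute-force oracle: enumerate every day of the span and count the days
  # landing on the 7-day sampling grid anchored at 4 January
  days <- seq(as.Date("1995-01-04"), as.Date("2020-12-31"), by = "day")
  n_weeks <- sum(as.numeric(days - days[1]) %% 7 == 0)
  expect_identical(nrow(w$prediction),
                   spec$n_stations * nrow(spec$depth_bins) * n_weeks)
  # at least weekly density over the span
  expect_gte(n_weeks, 52 * diff(spec$years))
})

test_that("weekly coverage is complete per stratum unless gaps are requested", {
  w <- generate_world(tiny_world_spec(seed = 4))
  counts <- table(w$prediction$station_id, w$prediction$depth_m)
  expect_true(all(counts == counts[1, 1]))
  wg <- generate_world(tiny_world_spec(seed = 4, gap_fraction = 0.25))
  expect_lt(nrow(wg$prediction), nrow(w$prediction))
})

test_that("training label counts match the spec with overlap allowed", {
  spec <- tiny_world_spec(seed = 6, n_train_ph = 250L, n_train_ta = 180L)
  w <- generate_world(spec)
  expect_identical(sum(!is.na(w$training$ph)), 250L)
  expect_identical(sum(!is.na(w$training$ta_umol_kg)), 180L)
  expect_true(all(!is.na(w$training$ph) | !is.na(w$training$ta_umol_kg)))
  expect_true(all(w$training$year_decimal >= spec$train_years[1] &
                  w$training$year_decimal <= spec$train_years[2]))
})

test_that("per-stratum planted pH trends lie in the study's printed range", {
  w <- generate_world(tiny_world_spec(seed = 1))
  expect_true(all(w$truth$trend_table$ph_trend >= -0.0042 &
                  w$truth$trend_table$ph_trend <= -0.0025))
  # surface acidifies fastest at every station
  tt <- w$truth$trend_table
  surf <- tt[tt$depth_m == min(tt$depth_m), ]
  deep <- tt[tt$depth_m == max(tt$depth_m), ]
  expect_true(all(surf$ph_trend[order(surf$station_id)] <
                  deep$ph_trend[order(deep$station_id)]))
})

test_that("a supplied per-stratum trend matrix is honoured through the fitted field", {
  tr <- matrix(-0.003, nrow = 6, ncol = 3)
  w <- generate_world(tiny_world_spec(seed = 1, ph_trend_per_year = tr))
  expect_equal(w$truth$trend_table$ph_trend, rep(-0.003, 18), tolerance = 1e-12)
  w2 <- generate_world(tiny_world_spec(seed = 1, ph_trend_per_year = 0))
  expect_true(all(w2$truth$trend_table$ph_trend == 0))
})

test_that("nutrients are high when pH is low (upwelling covariation)", {
  spec <- tiny_world_spec(seed = 9, noise_sd = zero_noise_sd(),
                          ph_trend_per_year = 0)
  w <- generate_world(spec)
  p <- w$prediction
  one <- p[p$station_id == p$station_id[1] & p$depth_m == p$depth_m[1], ]
  tl <- true_labels(w$truth, one)
  expect_lt(cor(tl$ph, one$nitrate_umol_kg), -0.95)
  expect_lt(cor(tl$ph, one$silicate_umol_kg), -0.95)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(tiny_world_spec(depth_bins = rbind(c(0, 5), c(4, 10))),
               "depth_bins")
  expect_error(tiny_world_spec(noise_sd = c(temperature = -1, salinity = 0,
                                            phosphate = 0, nitrate = 0,
                                            silicate = 0, ph = 0, ta = 0)),
               "noise_sd")
  expect_error(tiny_world_spec(years = c(2020, 1995)), "years")
  expect_error(tiny_world_spec(gap_fraction = 1.2), "gap_fraction")
  expect_error(tiny_world_spec(ph_trend_per_year = c(1, 2)),
               "ph_trend_per_year")
})

test_that("generated weeks are valid ISO weeks clipped to 52", {
  w <- generate_world(tiny_world_spec(seed = 10))
  expect_true(all(w$prediction$week >= 1 & w$prediction$week <= 52))
  expect_true(all(w$training$week >= 1 & w$training$week <= 52))
  # the clipping only affects genuine week-53 dates
  expect_identical(iso_week(as.Date("2015-12-31")), 52L) # ISO week 53
  expect_identical(iso_week(as.Date("2015-06-01")), 23L)
})

test_that("world specs round-trip through YAML and JSON files", {
  spec <- tiny_world_spec(seed = 3)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 3, n_train_ph = 400, n_train_ta = 300), yml)
  expect_identical(generate_world(world_spec_from_file(yml))$training,
                   generate_world(spec)$training)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 3, n_train_ph = 400, n_train_ta = 300,
                            depth_bins = list(c(0, 5), c(5, 10))),
                       js, auto_unbox = TRUE)
  w <- generate_world(world_spec_from_file(js))
  expect_identical(sort(unique(w$prediction$depth_m)), c(2.5, 7.5))
})
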