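# Conditions A-D, the classifier, forecast modes, and rainfall logic

params <- mcda_parameters() # Lmin 0.05, Umin 0.39, Amp 0.36

test_that("condition A keeps the closed [Lmin, Umin] interval and drops nodata", {
  mi <- composite_image(matrix(c(0.20, 0.02, 0.50, NA,
                                 0.05, 0.39, 0.049, 0.391), 2, 4), "min_mean")
  a <- condition_a(mi, params)
  expect_identical(a, matrix(c(TRUE, FALSE, FALSE, FALSE,
                               TRUE, TRUE, FALSE, FALSE), 2, 4))
  strict <- mcda_parameters(strict_inequalities = TRUE)
  expect_false(condition_a(mi, strict)[1, 3]) # 0.05 excluded under strict
})

test_that("condition B is closed at Amp so the calibrated value itself is admissible", {
  ai <- composite_image(matrix(c(0.60, 0.36, 0.10, NA), 2, 2), "amplitude")
  b <- condition_b(ai, params)
  expect_identical(b, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_false(condition_b(ai, mcda_parameters(strict_inequalities = TRUE))[2, 1])
})

test_that("classification is the conjunction of conditions A-D", {
  mi <- composite_image(matrix(c(0.20, 0.20, 0.55, 0.20), 2, 2), "min_mean")
  mx <- composite_image(matrix(c(0.80, 0.80, 0.75, 0.80), 2, 2), "max_mean")
  steep <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)     # pixel 2 on >12% slope
  managed <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)   # pixel 4 unmanaged
  map <- mcda_classify(mi, mx, params, terrain_mask = steep,
                       management_mask = managed)
  expect_identical(map$mask, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  with(map$conditions, expect_identical(map$mask, A & B & C & D))
  expect_true(all(map$mask[!steep] == FALSE))   # mask subset of condition C
  expect_true(all(map$mask[!managed] == FALSE)) # mask subset of condition D
})

test_that("classification is deterministic and pure", {
  scene <- generate_scene(dim = c(40, 40), seed = 7)
  m1 <- second_forecast(scene$series, 2006, params)
  m2 <- second_forecast(scene$series, 2006, params)
  expect_identical(m1$mask, m2$mask)
})

test_that("raising Amp or narrowing [Lmin, Umin] never adds soybean pixels", {
  scene <- generate_scene(dim = c(60, 60), seed = 3)
  sow <- select_window(scene$series, crop_year_windows(), "sowing", 2006)
  mx <- select_window(scene$series, crop_year_windows(), "maxdev", 2006)
  mi <- min_mean_evi(sow); ma <- max_mean_evi(mx)
  area <- function(p) sum(mcda_classify(mi, ma, p)$mask)
  amps <- seq(0.1, 0.7, 0.1)
  areas_amp <- vapply(amps, function(a) area(mcda_parameters(amp = a)), numeric(1))
  expect_true(all(diff(areas_amp) <= 0))
  narrowings <- lapply(seq(0, 0.12, 0.03), function(d) {
    mcda_parameters(lmin = 0.05 + d, umin = 0.39 - d)
  })
  areas_win <- vapply(narrowings, area, numeric(1))
  expect_true(all(diff(areas_win) <= 0))
})

test_that("parameter invariants are enforced", {
  expect_error(mcda_parameters(lmin = 0.4, umin = 0.39), "lmin")
  expect_error(mcda_parameters(amp = 0), "amp")
})

test_that("second forecast recovers the true map exactly on a noise-free scene", {
  scene <- generate_scene(default_land_cover_specs(noise_sd = 0),
                          dim = c(80, 80), steep_frac = 0, seed = 11)
  map <- second_forecast(scene$series, 2006, params)
  int <- scene$truth$interior_mask
  expect_identical(map$mask[int], scene$truth$soybean_mask[int])
})

test_that("first and second forecasts agree on pixels with stationary phenology", {
  scene <- generate_scene(default_land_cover_specs(noise_sd = 0),
                          dim = c(60, 60), steep_frac = 0, seed = 5)
  m2 <- second_forecast(scene$series, 2006, params)
  m1 <- first_forecast(scene$series, 2006, params)
  expect_true(m1$fallback_used)
  expect_identical(m1$mask, m2$mask)
})

test_that("first forecast errors for the earliest archived crop year", {
  scene <- generate_scene(dim = c(20, 20), seed = 2)
  expect_error(first_forecast(scene$series, 2005, params),
               "first forecast unavailable")
})

test_that("a pixel newly converted to soybean is missed by the first forecast", {
  # prior year: low-peak cotton phenology; current year: soybean phenology
  specs <- default_land_cover_specs(noise_sd = 0)
  doys_prior <- maxdev_tags(2005)
  prior_vals <- evi_curve(specs$cotton_single, doys_prior$doy)
  tags_cur <- rbind(data.frame(year = 2006L, doy = seq(225L, 353L, 16L)),
                    data.frame(year = 2007L, doy = c(1L, 17L, 33L)))
  cur_vals <- evi_curve(specs$soybean_single, tags_cur$doy)
  series <- constant_series(c(prior_vals, cur_vals),
                            c(doys_prior$year, tags_cur$year),
                            c(doys_prior$doy, tags_cur$doy))
  m1 <- first_forecast(series, 2006, params)
  m2 <- second_forecast(series, 2006, params)
  expect_false(any(m1$mask))  # prior-year peak too low: conversion missed
  expect_true(all(m2$mask))   # current-year peak sees the new field
})

test_that("water deficit triggers the prior-normal-year fallback in the second forecast", {
  scene <- generate_scene(default_land_cover_specs(noise_sd = 0),
                          dim = c(30, 30), steep_frac = 0, seed = 9)
  dry <- generate_rainfall(deficit = TRUE, seed = 4, year = 2006)
  wet <- generate_rainfall(deficit = FALSE, seed = 4, year = 2006)
  m_dry <- second_forecast(scene$series, 2006, params, rain = dry)
  m_wet <- second_forecast(scene$series, 2006, params, rain = wet)
  expect_true(m_dry$fallback_used)
  expect_false(m_wet$fallback_used)
  expect_identical(m_dry$mask, m_wet$mask) # stationary scene: same map
})

test_that("water deficit is a 30-day span without a >10 mm event", {
  start <- as.Date("2006-09-01")
  dry40 <- rainfall_series(seq(start, by = 10, length.out = 4), rep(8, 4))
  expect_true(water_deficit(dry40, start, start + 39))

  regular <- rainfall_series(seq(start, by = 10, length.out = 6), rep(12, 6))
  expect_false(water_deficit(regular, start, start + 59))

  # 25 dry days, one 15 mm event, 25 dry days: no 30-day dry span
  mid <- rainfall_series(seq(start, by = 5, length.out = 11),
                         c(rep(2, 5), 15, rep(2, 5)))
  expect_false(water_deficit(mid, start, start + 50))

  expect_error(water_deficit(rainfall_series(start, 5)[0, ]), "empty")
})

test_that("sowing onset is the first dekad at/after 1 September reaching the threshold", {
  start <- as.Date("2006-09-01")
  dates <- seq(start, by = 10, length.out = 6)
  rain <- rainfall_series(dates, c(2, 5, 30, 40, 3, 50))
  expect_equal(sowing_onset(rain), dates[3])
  expect_true(is.na(sowing_onset(rainfall_series(dates, rep(1, 6)))))
  expect_equal(sowing_onset(rain, threshold_mm = 0), dates[1])
})
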