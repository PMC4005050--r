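# MinMean / MaxMean / Amplitude operators and calendar-window selection

test_that("window selection honours the sowing and wrap-around maxdev windows", {
  tags <- rbind(
    data.frame(year = 2006L, doy = seq(225L, 353L, 16L)),
    data.frame(year = 2007L, doy = c(1L, 17L, 33L))
  )
  series <- constant_series(seq(0.1, by = 0.01, length.out = nrow(tags)),
                            tags$year, tags$doy)
  w <- crop_year_windows()

  sow <- select_window(series, w, "sowing", 2006)
  expect_equal(series_tags(sow),
               data.frame(year = 2006L, doy = seq(225L, 337L, 16L)))

  mx <- select_window(series, w, "maxdev", 2006)
  expect_equal(series_tags(mx), maxdev_tags(2006), ignore_attr = TRUE)

  no_sow <- constant_series(c(0.5, 0.6), c(2006L, 2007L), c(353L, 17L))
  expect_error(select_window(no_sow, w, "sowing", 2006), "empty sowing window")
})

test_that("window construction rejects overlapping or wrapping-sowing setups", {
  expect_error(crop_year_windows(sowing_start_doy = 337, sowing_end_doy = 225),
               "wrap")
  expect_error(crop_year_windows(maxdev_start_doy = 300, maxdev_end_doy = 360,
                                 sowing_start_doy = 225, sowing_end_doy = 337),
               "overlap")
})

test_that("min_mean is the minimum over consecutive-pair means with nodata fallback", {
  s <- constant_series(c(0.30, 0.10, 0.50), 2006L, sowing_doys[1:3])
  expect_equal(min_mean_evi(s)$values, matrix(0.20, 2, 2))

  const <- constant_series(c(0.25, 0.25, 0.25), 2006L, sowing_doys[1:3])
  expect_equal(min_mean_evi(const)$values, matrix(0.25, 2, 2))

  # masked middle composite: pair means fall back to the surviving member
  v2 <- matrix(NA_real_, 2, 2)
  holey <- composite_series(list(
    evi_composite(matrix(0.30, 2, 2), 2006L, 225L, 1),
    evi_composite(v2, 2006L, 241L, 1),
    evi_composite(matrix(0.50, 2, 2), 2006L, 257L, 1)
  ))
  expect_equal(min_mean_evi(holey)$values, matrix(0.30, 2, 2))

  expect_error(min_mean_evi(constant_series(0.3, 2006L, 225L)),
               "at least two composites")
})

test_that("min_mean is order-sensitive: pairs are consecutive in time", {
  a <- constant_series(c(0.10, 0.50, 0.10), 2006L, sowing_doys[1:3])
  b <- constant_series(c(0.10, 0.10, 0.50), 2006L, sowing_doys[1:3])
  expect_equal(min_mean_evi(a)$values[1, 1], 0.30)
  expect_equal(min_mean_evi(b)$values[1, 1], 0.10)
})

test_that("max_mean averages four composites, excludes masked values, enforces strictness", {
  tg <- maxdev_tags(2006)
  s <- constant_series(c(0.70, 0.80, 0.90, 0.80), tg$year, tg$doy)
  expect_equal(max_mean_evi(s)$values, matrix(0.80, 2, 2))

  holey <- composite_series(list(
    evi_composite(matrix(0.80, 2, 2), 2006L, 353L, 1),
    evi_composite(matrix(NA_real_, 2, 2), 2007L, 1L, 1),
    evi_composite(matrix(0.80, 2, 2), 2007L, 17L, 1),
    evi_composite(matrix(0.80, 2, 2), 2007L, 33L, 1)
  ))
  expect_equal(max_mean_evi(holey)$values, matrix(0.80, 2, 2))

  three <- constant_series(c(0.7, 0.8, 0.9), tg$year[1:3], tg$doy[1:3])
  expect_error(max_mean_evi(three, strict = TRUE), "four composites")
  expect_message(lenient <- max_mean_evi(three, strict = FALSE), "lenient")
  expect_equal(lenient$values[1, 1], 0.8)

  five <- constant_series(c(0.9, 0.7, 0.7, 0.7, 0.1),
                          c(2006L, 2007L, 2007L, 2007L, 2007L),
                          c(353L, 1L, 17L, 33L, 49L))
  expect_warning(m5 <- max_mean_evi(five), "first four")
  expect_equal(m5$values[1, 1], 0.75) # DOY 49 extra ignored
})

test_that("amplitude subtracts elementwise, propagates nodata, is not clamped", {
  mk <- function(v, kind) composite_image(matrix(v, 2, 2), kind)
  expect_equal(evi_amplitude(mk(0.80, "max_mean"), mk(0.20, "min_mean"))$values,
               matrix(0.60, 2, 2))
  expect_equal(evi_amplitude(mk(0.30, "max_mean"), mk(0.30, "min_mean"))$values,
               matrix(0.00, 2, 2))
  expect_equal(evi_amplitude(mk(0.20, "max_mean"), mk(0.50, "min_mean"))$values,
               matrix(-0.30, 2, 2)) # negative amplitude preserved
  expect_true(all(is.na(
    evi_amplitude(mk(NA_real_, "max_mean"), mk(0.20, "min_mean"))$values
  )))
  expect_error(
    evi_amplitude(mk(0.8, "max_mean"),
                  composite_image(matrix(0.2, 3, 3), "min_mean")),
    "different grids"
  )
  expect_error(evi_amplitude(mk(0.8, "min_mean"), mk(0.2, "min_mean")),
               "max_mean")
})

test_that("min_mean never exceeds the global pair-mean average on mask-free input", {
  for (seed in 1:5) {
    s <- random_series(4, 4, 6, seed = seed, na_frac = 0)
    vals <- lapply(s$composites, `[[`, "values")
    pair_means <- lapply(seq_len(5), function(i) (vals[[i]] + vals[[i + 1]]) / 2)
    global_avg <- Reduce(`+`, pair_means) / length(pair_means)
    expect_true(all(min_mean_evi(s)$values <= global_avg + 1e-12))
  }
})

test_that("image operators are idempotent on a constant series", {
  s <- constant_series(rep(0.4, 4), 2006L, sowing_doys[1:4])
  expect_equal(min_mean_evi(s)$values, matrix(0.4, 2, 2))
  expect_equal(max_mean_evi(s)$values, matrix(0.4, 2, 2))
  expect_equal(evi_amplitude(max_mean_evi(s), min_mean_evi(s))$values,
               matrix(0, 2, 2))
})

test_that("vectorized compositing equals brute-force per-pixel loops on random stacks", {
  for (seed in 1:6) {
    s <- random_series(8, 8, 6, seed = seed, na_frac = 0.15)
    expect_identical(min_mean_evi(s)$values, brute_min_mean(s))
    suppressWarnings(mm <- max_mean_evi(s))
    expect_identical(mm$values, brute_max_mean(s))
  }
})

test_that("composite constructor validates range, scaling and the 16-day grid", {
  expect_error(evi_composite(matrix(5, 2, 2), 2006, 225, scale_factor = 1),
               "plausible range")
  auto <- evi_composite(matrix(c(2000L, -1500L, 8000L, 100L), 2, 2), 2006, 225)
  expect_equal(auto$scale_factor, 1e-4)
  expect_equal(auto$values[1, 1], 0.2)
  expect_warning(evi_composite(matrix(0.2, 2, 2), 2006, 230), "16-day grid")
  expect_error(
    composite_series(list(
      evi_composite(matrix(0.2, 2, 2), 2006, 225),
      evi_composite(matrix(0.2, 2, 2), 2006, 225)
    )),
    "duplicate"
  )
  expect_error(
    composite_series(list(
      evi_composite(matrix(0.2, 2, 2), 2006, 225),
      evi_composite(matrix(0.2, 3, 3), 2006, 241)
    )),
    "grid dimensions"
  )
})
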