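# EVI composite containers and the MinMean / MaxMean / Amplitude operators.

#' Single 16-day EVI composite
#'
#' Wraps one 2-D grid of Enhanced Vegetation Index values tagged with the
#' calendar year and the day-of-year (DOY) on which the 16-day compositing
#' window starts. Missing observations are `NA`. Values stored as scaled
#' integers (the usual 1e-4 convention for the 16-day product) are detected
#' automatically and converted to floats; pass `scale_factor` to override.
#'
#' @param values numeric matrix of EVI values; `NA` marks nodata.
#' @param year calendar year of the composite.
#' @param doy day-of-year of the composite start (1-366). The standard 16-day
#'   grid uses DOY 1, 17, 33, ..., 353; other values are accepted with a
#'   warning.
#' @param scale_factor multiplier applied to `values` (1 if already float;
#'   `NULL` to auto-detect integer-scaled input).
#' @return an object of class `evi_composite`.
#' @export
evi_composite <- function(values, year, doy, scale_factor = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  year <- as.integer(year)
  doy <- as.integer(doy)
  if (doy < 1L || doy > 366L) stop("doy must be in 1..366")
  if (!(doy %in% seq(1L, 353L, by = 16L))) {
    warning(sprintf("doy %d is not on the standard 16-day grid (1, 17, ..., 353)", doy))
  }
  if (is.null(scale_factor)) {
    v <- values[!is.na(values)]
    scale_factor <- if (length(v) && all(v == round(v)) && any(abs(v) > 2)) 1e-4 else 1
  }
  if (scale_factor != 1) values <- values * scale_factor
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -0.3 || max(v) > 1.1)) {
    stop("scaled EVI values outside the plausible range [-0.3, 1.1]")
  }
  structure(
    list(values = values, year = year, doy = doy, scale_factor = scale_factor),
    class = "evi_composite"
  )
}

#' Ordered stack of EVI composites on one shared grid
#'
#' @param composites list of [evi_composite()] objects sharing one grid.
#'   Sorted by (year, doy); duplicate tags are an error.
#' @param pixel_area_ha area of one pixel in hectares (6.25 ha for the 250 m
#'   product).
#' @param geotransform,crs optional georeferencing metadata, carried opaquely.
#' @return an object of class `composite_series`.
#' @export
composite_series <- function(composites, pixel_area_ha = 6.25,
                             geotransform = NULL, crs = NULL) {
  stopifnot(is.list(composites), length(composites) >= 1)
  ok <- vapply(composites, inherits, logical(1), "evi_composite")
  if (!all(ok)) stop("all elements must be evi_composite objects")
  dims <- vapply(composites, function(c) dim(c$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all composites must share identical grid dimensions")
  }
  years <- vapply(composites, `[[`, integer(1), "year")
  doys <- vapply(composites, `[[`, integer(1), "doy")
  key <- years * 1000L + doys
  if (anyDuplicated(key)) stop("duplicate (year, doy) composite tags")
  composites <- composites[order(key)]
  structure(
    list(
      composites = composites,
      nrow = dims[1, 1], ncol = dims[2, 1],
      pixel_area_ha = pixel_area_ha,
      geotransform = geotransform, crs = crs
    ),
    class = "composite_series"
  )
}

#' @export
length.composite_series <- function(x) length(x$composites)

#' Tags of a composite series
#'
#' @param series a [composite_series()].
#' @return data.frame with columns `year` and `doy`, one row per composite.
#' @export
series_tags <- function(series) {
  stopifnot(inherits(series, "composite_series"))
  data.frame(
    year = vapply(series$composites, `[[`, integer(1), "year"),
    doy = vapply(series$composites, `[[`, integer(1), "doy")
  )
}

#' Crop-year calendar windows
#'
#' The two fixed windows the classifier reads from the composite stack: the
#' sowing window (DOY 225-337, mid-August to early December) and the maximum
#' crop development window (DOY 353-33, wrapping the year boundary into
#' January of the following calendar year).
#'
#' @param sowing_start_doy,sowing_end_doy sowing window bounds (inclusive).
#' @param maxdev_start_doy,maxdev_end_doy maximum-development window bounds;
#'   `maxdev_end_doy < maxdev_start_doy` signals the year-boundary wrap.
#' @param crop_year_label optional label like `"2006/2007"`.
#' @return an object of class `crop_year_windows`.
#' @export
crop_year_windows <- function(sowing_start_doy = 225, sowing_end_doy = 337,
                              maxdev_start_doy = 353, maxdev_end_doy = 33,
                              crop_year_label = NULL) {
  w <- list(
    sowing_start_doy = as.integer(sowing_start_doy),
    sowing_end_doy = as.integer(sowing_end_doy),
    maxdev_start_doy = as.integer(maxdev_start_doy),
    maxdev_end_doy = as.integer(maxdev_end_doy),
    crop_year_label = crop_year_label
  )
  if (w$sowing_start_doy > w$sowing_end_doy) {
    stop("sowing window must not wrap the year boundary")
  }
  # overlap check: the (possibly wrapping) maxdev window must not intersect
  # the sowing window
  maxdev_doys <- if (w$maxdev_end_doy < w$maxdev_start_doy) {
    c(w$maxdev_start_doy:366, 1:w$maxdev_end_doy)
  } else {
    w$maxdev_start_doy:w$maxdev_end_doy
  }
  if (any(maxdev_doys >= w$sowing_start_doy & maxdev_doys <= w$sowing_end_doy)) {
    stop("sowing and maximum-development windows overlap")
  }
  structure(w, class = "crop_year_windows")
}

#' Select the composites of one calendar window of a crop year
#'
#' The sowing window takes composites of the crop year itself; the
#' maximum-development window wraps the year boundary (DOY >= start of year
#' `crop_year` plus DOY <= end of year `crop_year + 1`).
#'
#' @param series a [composite_series()].
#' @param windows a [crop_year_windows()].
#' @param which `"sowing"` or `"maxdev"`.
#' @param crop_year calendar year in which the crop year starts (2006 for
#'   crop year 2006/2007).
#' @return a [composite_series()] restricted to the window.
#' @export
select_window <- function(series, windows, which = c("sowing", "maxdev"),
                          crop_year) {
  stopifnot(inherits(series, "composite_series"),
            inherits(windows, "crop_year_windows"))
  which <- match.arg(which)
  tags <- series_tags(series)
  keep <- if (which == "sowing") {
    tags$year == crop_year &
      tags$doy >= windows$sowing_start_doy & tags$doy <= windows$sowing_end_doy
  } else if (windows$maxdev_end_doy < windows$maxdev_start_doy) {
    (tags$year == crop_year & tags$doy >= windows$maxdev_start_doy) |
      (tags$year == crop_year + 1 & tags$doy <= windows$maxdev_end_doy)
  } else {
    tags$year == crop_year &
      tags$doy >= windows$maxdev_start_doy & tags$doy <= windows$maxdev_end_doy
  }
  if (!any(keep)) {
    stop(sprintf("empty %s window for crop year %d/%d", which,
                 crop_year, crop_year + 1))
  }
  composite_series(series$composites[keep],
                   pixel_area_ha = series$pixel_area_ha,
                   geotransform = series$geotransform, crs = series$crs)
}

#' Derived composite image (MinMeanEVI, MaxMeanEVI or AmpEVI)
#'
#' @param values numeric matrix.
#' @param kind one of `"min_mean"`, `"max_mean"`, `"amplitude"`.
#' @param source_tags data.frame of (year, doy) tags the image was built from.
#' @return an object of class `composite_image`.
#' @export
composite_image <- function(values, kind = c("min_mean", "max_mean", "amplitude"),
                            source_tags = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  kind <- match.arg(kind)
  structure(list(values = values, kind = kind, source_tags = source_tags),
            class = "composite_image")
}

#' Minimum-mean EVI image over the sowing window
#'
#' Consecutive composites are averaged two by two (pair means); the per-pixel
#' minimum over all pair means is returned. A pixel masked in one member of a
#' pair falls back to the surviving member (the 16-day product is already
#' maximum-value composited, so a lone value is trusted); a pixel masked in
#' every pair is nodata. The minimum of pair means smoothes the profile over
#' a short window while still tracking the pre-sowing EVI trough.
#'
#' Note the operator is sensitive to composite order: pairs are consecutive
#' in (year, doy) order, so permuting the stack changes the pair means.
#'
#' @param sowing_series a [composite_series()] restricted to the sowing
#'   window; at least two composites.
#' @return a `min_mean` [composite_image()].
#' @export
min_mean_evi <- function(sowing_series) {
  stopifnot(inherits(sowing_series, "composite_series"))
  n <- length(sowing_series)
  if (n < 2) stop("min_mean requires at least two composites")
  vals <- lapply(sowing_series$composites, `[[`, "values")
  out <- NULL
  for (i in seq_len(n - 1)) {
    a <- vals[[i]]
    b <- vals[[i + 1]]
    pm <- (a + b) / 2
    pm[is.na(a)] <- b[is.na(a)] # fallback to the surviving member
    pm[is.na(b) & !is.na(a)] <- a[is.na(b) & !is.na(a)]
    out <- if (is.null(out)) pm else pmin(out, pm, na.rm = TRUE)
  }
  composite_image(out, "min_mean", series_tags(sowing_series))
}

#' Maximum-mean EVI image over the maximum-development window
#'
#' The four consecutive composites starting at the window opening (DOY 353)
#' are averaged per pixel; masked values are excluded from the mean, and a
#' pixel masked in all four is nodata. With more than four composites in the
#' window the extras are ignored with a warning; with fewer, `strict = TRUE`
#' (the default) errors while `strict = FALSE` averages what exists.
#'
#' @param maxdev_series a [composite_series()] restricted to the
#'   maximum-development window.
#' @param strict error when fewer than four composites are available.
#' @return a `max_mean` [composite_image()].
#' @export
max_mean_evi <- function(maxdev_series, strict = TRUE) {
  stopifnot(inherits(maxdev_series, "composite_series"))
  n <- length(maxdev_series)
  if (n == 0) stop("no usable images in the maximum-development window")
  if (n > 4) {
    warning(sprintf("using the first four of %d composites in the maximum-development window", n))
    maxdev_series <- composite_series(maxdev_series$composites[1:4],
                                      pixel_area_ha = maxdev_series$pixel_area_ha)
    n <- 4
  }
  if (n < 4) {
    if (strict) stop(sprintf("max_mean requires four composites (got %d)", n))
    message(sprintf("max_mean averaging %d composites (lenient mode)", n))
  }
  vals <- lapply(maxdev_series$composites, `[[`, "values")
  sum_v <- Reduce(`+`, lapply(vals, function(v) ifelse(is.na(v), 0, v)))
  cnt <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
  out <- sum_v / cnt
  out[cnt == 0] <- NA_real_
  composite_image(out, "max_mean", series_tags(maxdev_series))
}

#' EVI amplitude image
#'
#' Elementwise MaxMeanEVI minus MinMeanEVI. Nodata on either side propagates.
#' Negative amplitudes (possible on scenes where the peak window does not
#' dominate) are preserved, not clamped.
#'
#' @param max_img a `max_mean` [composite_image()].
#' @param min_img a `min_mean` [composite_image()] on the same grid.
#' @return an `amplitude` [composite_image()].
#' @export
evi_amplitude <- function(max_img, min_img) {
  stopifnot(inherits(max_img, "composite_image"),
            inherits(min_img, "composite_image"))
  if (max_img$kind != "max_mean" || min_img$kind != "min_mean") {
    stop("amplitude requires a max_mean and a min_mean image")
  }
  if (!identical(dim(max_img$values), dim(min_img$values))) {
    stop("max and min images are on different grids")
  }
  composite_image(max_img$values - min_img$values, "amplitude",
                  rbind(max_img$source_tags, min_img$source_tags))
}
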