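# Threshold parameters, conditions A-D, and the two forecast modes.

#' Calibrated MCDA threshold parameters
#'
#' `lmin` and `umin` bound the MinMeanEVI of crop pixels (condition A):
#' pixels below `lmin` are cloud shadow or water, pixels above `umin` are
#' perennial natural vegetation. `amp` is the minimum EVI amplitude
#' (MaxMean - MinMean) at which a pixel - including mixed field-border
#' pixels - is still designated soybean (condition B).
#' `slope_threshold_pct` excludes terrain too steep for mechanized farming
#' (condition C). The shipped defaults (0.05, 0.39, 0.36) are the operational
#' values calibrated for Mato Grosso; note that by definition the lower bound
#' 0.05 is Lmin and 0.39 is Umin (Lmin < Umin always).
#'
#' Once attached to a multi-year run the set is meant to be immutable: the
#' same thresholds are applied to every crop year (see
#' [freeze_parameters()]).
#'
#' @param lmin lower MinMeanEVI bound (EVI units).
#' @param umin upper MinMeanEVI bound (EVI units); must exceed `lmin`.
#' @param amp minimum amplitude (EVI units); must be positive.
#' @param slope_threshold_pct percent-slope limit for mechanization.
#' @param strict_inequalities use open intervals (`lmin < x < umin`,
#'   `amplitude > amp`) instead of the default closed ones.
#' @return an object of class `mcda_parameters`.
#' @export
mcda_parameters <- function(lmin = 0.05, umin = 0.39, amp = 0.36,
                            slope_threshold_pct = 12,
                            strict_inequalities = FALSE) {
  if (!(lmin < umin)) stop("lmin must be strictly below umin")
  if (!(amp > 0)) stop("amp must be positive")
  structure(
    list(lmin = lmin, umin = umin, amp = amp,
         slope_threshold_pct = slope_threshold_pct,
         strict_inequalities = isTRUE(strict_inequalities)),
    class = "mcda_parameters"
  )
}

#' @export
print.mcda_parameters <- function(x, ...) {
  cat(sprintf(
    "MCDA parameters: Lmin = %.3f, Umin = %.3f, Amp = %.3f, slope <= %.1f%%%s\n",
    x$lmin, x$umin, x$amp, x$slope_threshold_pct,
    if (x$strict_inequalities) " (strict inequalities)" else ""
  ))
  invisible(x)
}

#' Condition A: sowing-window EVI trough inside [Lmin, Umin]
#'
#' @param min_img a `min_mean` [composite_image()].
#' @param params an [mcda_parameters()] object.
#' @return logical matrix; `FALSE` on nodata.
#' @export
condition_a <- function(min_img, params) {
  stopifnot(inherits(min_img, "composite_image"), min_img$kind == "min_mean",
            inherits(params, "mcda_parameters"))
  v <- min_img$values
  m <- if (params$strict_inequalities) {
    v > params$lmin & v < params$umin
  } else {
    v >= params$lmin & v <= params$umin
  }
  m[is.na(m)] <- FALSE
  m
}

#' Condition B: EVI amplitude at or above Amp
#'
#' @param amp_img an `amplitude` [composite_image()].
#' @param params an [mcda_parameters()] object.
#' @return logical matrix; `FALSE` on nodata.
#' @export
condition_b <- function(amp_img, params) {
  stopifnot(inherits(amp_img, "composite_image"), amp_img$kind == "amplitude",
            inherits(params, "mcda_parameters"))
  v <- amp_img$values
  m <- if (params$strict_inequalities) v > params$amp else v >= params$amp
  m[is.na(m)] <- FALSE
  m
}

#' Classify a crop year into a binary soybean map
#'
#' A pixel is soybean iff it satisfies all four conditions: A (MinMeanEVI in
#' `[lmin, umin]`), B (amplitude >= `amp`), C (mechanizable terrain) and D
#' (management mask, all-true when not supplied). The result is a pure
#' function of its inputs; reruns are bit-identical.
#'
#' @param min_img a `min_mean` [composite_image()].
#' @param max_img a `max_mean` [composite_image()] on the same grid.
#' @param params an [mcda_parameters()] object.
#' @param terrain_mask logical matrix, `TRUE` = mechanizable (condition C);
#'   `NULL` for all-true.
#' @param management_mask logical matrix, `TRUE` = managed agricultural land
#'   (condition D); `NULL` for all-true.
#' @param mode forecast mode label, `"second"` or `"first"`.
#' @param crop_year_label optional label like `"2006/2007"`.
#' @param fallback_used whether prior-year peak images were substituted.
#' @param keep_conditions retain the per-condition masks for diagnostics.
#' @return an object of class `soybean_map` with elements `mask` (logical
#'   grid, `TRUE` = soybean), `nodata` (logical grid), `mode`,
#'   `fallback_used`, `params`, `conditions`, `crop_year_label`.
#' @export
mcda_classify <- function(min_img, max_img, params,
                          terrain_mask = NULL, management_mask = NULL,
                          mode = c("second", "first"),
                          crop_year_label = NULL,
                          fallback_used = FALSE,
                          keep_conditions = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "mcda_parameters"))
  dims <- dim(min_img$values)
  if (!identical(dims, dim(max_img$values))) stop("min and max images differ in grid")
  if (is.null(terrain_mask)) terrain_mask <- matrix(TRUE, dims[1], dims[2])
  if (is.null(management_mask)) management_mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dims, dim(terrain_mask)) || !identical(dims, dim(management_mask))) {
    stop("condition masks differ in grid")
  }
  amp_img <- evi_amplitude(max_img, min_img)
  A <- condition_a(min_img, params)
  B <- condition_b(amp_img, params)
  C <- terrain_mask & !is.na(terrain_mask)
  C[is.na(terrain_mask)] <- FALSE
  D <- management_mask & !is.na(management_mask)
  D[is.na(management_mask)] <- FALSE
  mask <- A & B & C & D
  nodata <- is.na(min_img$values) | is.na(max_img$values)
  structure(
    list(
      mask = mask, nodata = nodata,
      mode = mode, fallback_used = isTRUE(fallback_used),
      crop_year_label = crop_year_label,
      params = params,
      conditions = if (keep_conditions) list(A = A, B = B, C = C, D = D),
      source_tags = list(min = min_img$source_tags, max = max_img$source_tags)
    ),
    class = "soybean_map"
  )
}

#' @export
print.soybean_map <- function(x, ...) {
  cat(sprintf(
    "Soybean map %s (%s forecast%s): %d x %d pixels, %d soybean (%.1f%%), %d nodata\n",
    if (is.null(x$crop_year_label)) "" else x$crop_year_label,
    x$mode, if (x$fallback_used) ", prior-year peak fallback" else "",
    nrow(x$mask), ncol(x$mask), sum(x$mask),
    100 * mean(x$mask), sum(x$nodata)
  ))
  invisible(x)
}

#' Soybean area of a map in hectares
#'
#' @param map a `soybean_map`.
#' @param pixel_area_ha hectares per pixel.
#' @return numeric scalar, `sum(mask) * pixel_area_ha`.
#' @export
soybean_area_ha <- function(map, pixel_area_ha = 6.25) {
  stopifnot(inherits(map, "soybean_map"))
  sum(map$mask) * pixel_area_ha
}

crop_year_label <- function(crop_year) sprintf("%d/%d", crop_year, crop_year + 1)

# shared engine for both forecast modes: the MinMean image always comes from
# the current crop year's sowing window; `max_year` says which crop year's
# maximum-development window supplies the MaxMean image.
forecast_engine <- function(series, crop_year, max_year, windows, params,
                            terrain_mask, management_mask, mode,
                            fallback_used, strict_maxdev = TRUE) {
  sow <- select_window(series, windows, "sowing", crop_year)
  mx <- select_window(series, windows, "maxdev", max_year)
  mcda_classify(
    min_mean_evi(sow), max_mean_evi(mx, strict = strict_maxdev), params,
    terrain_mask = terrain_mask, management_mask = management_mask,
    mode = mode, crop_year_label = crop_year_label(crop_year),
    fallback_used = fallback_used
  )
}

# most recent prior crop year with a usable maximum-development window, not
# itself flagged as a water-deficit year
prior_normal_year <- function(series, crop_year, windows, deficit_years) {
  tags <- series_tags(series)
  for (y in sort(unique(tags$year[tags$year < crop_year]), decreasing = TRUE)) {
    if (y %in% deficit_years) next
    has_maxdev <- any(
      (tags$year == y & tags$doy >= windows$maxdev_start_doy) |
        (tags$year == y + 1 & tags$doy <= windows$maxdev_end_doy)
    )
    if (has_maxdev) return(y)
  }
  NA_integer_
}

#' Second forecast (released by early February)
#'
#' MinMeanEVI and MaxMeanEVI both come from the current crop year. If a
#' rainfall series is supplied and a water deficit is detected in the growing
#' season (see [water_deficit()]), or the current year's
#' maximum-development window is empty or unusable, the peak images of the
#' most recent prior normal crop year are substituted and `fallback_used` is
#' set.
#'
#' @param series a [composite_series()] covering the needed windows.
#' @param crop_year starting calendar year of the crop year.
#' @param params an [mcda_parameters()] object.
#' @param windows a [crop_year_windows()].
#' @param terrain_mask,management_mask optional condition C / D masks.
#' @param rain optional [rainfall_series()] used for the water-deficit check.
#' @param deficit_years integer years known to be water-deficit years,
#'   excluded when picking the fallback year.
#' @param strict_maxdev require four peak-window composites.
#' @return a `soybean_map`.
#' @export
second_forecast <- function(series, crop_year, params,
                            windows = crop_year_windows(),
                            terrain_mask = NULL, management_mask = NULL,
                            rain = NULL, deficit_years = integer(),
                            strict_maxdev = TRUE) {
  deficit <- FALSE
  if (!is.null(rain)) {
    deficit <- water_deficit(
      rain,
      start = as.Date(sprintf("%d-09-01", crop_year)),
      end = as.Date(sprintf("%d-01-31", crop_year + 1))
    )
  }
  if (!deficit) {
    ok <- tryCatch({
      forecast_engine(series, crop_year, crop_year, windows, params,
                      terrain_mask, management_mask, "second",
                      fallback_used = FALSE, strict_maxdev = strict_maxdev)
    }, error = function(e) e)
    if (!inherits(ok, "error")) return(ok)
  }
  y <- prior_normal_year(series, crop_year,  windows,
                         c(deficit_years, if (deficit) crop_year))
  if (is.na(y)) {
    stop(sprintf("no usable maximum-development images for crop year %s and no prior normal year available",
                 crop_year_label(crop_year)))
  }
  forecast_engine(series, crop_year, y, windows, params,
                  terrain_mask, management_mask, "second",
                  fallback_used = TRUE, strict_maxdev = strict_maxdev)
}

#' First forecast (released in early December)
#'
#' MinMeanEVI comes from the current crop year's sowing window, while
#' MaxMeanEVI is taken from the most recent prior normal crop year (the
#' current peak window has not been observed yet in December). For the
#' earliest archived crop year no first forecast exists.
#'
#' A documented limitation: pixels newly converted to soybean in the current
#' year carry the prior year's low peak EVI and are missed by this mode.
#'
#' @inheritParams second_forecast
#' @return a `soybean_map` with `fallback_used = TRUE`.
#' @export
first_forecast <- function(series, crop_year, params,
                           windows = crop_year_windows(),
                           terrain_mask = NULL, management_mask = NULL,
                           deficit_years = integer(),
                           strict_maxdev = TRUE) {
  y <- prior_normal_year(series, crop_year, windows, deficit_years)
  if (is.na(y)) {
    stop(sprintf("first forecast unavailable for crop year %s: no prior crop year in the archive",
                 crop_year_label(crop_year)))
  }
  forecast_engine(series, crop_year, y, windows, params,
                  terrain_mask, management_mask, "first",
                  fallback_used = TRUE, strict_maxdev = strict_maxdev)
}
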