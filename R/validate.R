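# Zonal area estimation, expansion mapping, and the accuracy-assessment
# protocol (stratified sampling, confusion matrix, Kappa, regression
# diagnostics against official statistics).

#' Zone map for per-municipality aggregation
#'
#' @param zone_ids integer matrix aligned to the classification grid; 0
#'   marks pixels outside every zone.
#' @param zone_names optional named character vector or data.frame
#'   (`zone_id`, `zone_name`); names are auto-generated when absent.
#' @return an object of class `zone_map`.
#' @export
zone_map <- function(zone_ids, zone_names = NULL) {
  stopifnot(is.matrix(zone_ids))
  storage.mode(zone_ids) <- "integer"
  if (any(zone_ids < 0L, na.rm = TRUE)) stop("zone ids must be >= 0")
  ids <- sort(unique(zone_ids[zone_ids > 0L]))
  if (is.null(zone_names)) {
    zone_names <- stats::setNames(sprintf("zone_%d", ids), ids)
  } else if (is.data.frame(zone_names)) {
    zone_names <- stats::setNames(as.character(zone_names$zone_name),
                                  zone_names$zone_id)
  }
  missing <- setdiff(as.character(ids), names(zone_names))
  if (length(missing)) {
    stop(sprintf("zone ids without a name: %s", paste(missing, collapse = ", ")))
  }
  structure(list(zone_ids = zone_ids, zone_names = zone_names),
            class = "zone_map")
}

#' Per-zone soybean area table
#'
#' Counts soybean pixels per zone and converts to hectares. Every named zone
#' appears, including zones with zero soybean; pixels with zone id 0 are
#' collected in a reserved `unzoned` row so that the zone totals conserve
#' the map total.
#'
#' @param map a `soybean_map`.
#' @param zones a [zone_map()] on the same grid.
#' @param pixel_area_ha hectares per pixel (default 6.25).
#' @return data.frame with columns `zone_id`, `zone_name`, `crop_year`,
#'   `pixel_count`, `soybean_area_ha`, `forecast_mode`.
#' @export
zonal_area <- function(map, zones, pixel_area_ha = 6.25) {
  stopifnot(inherits(map, "soybean_map"), inherits(zones, "zone_map"))
  if (!identical(dim(map$mask), dim(zones$zone_ids))) {
    stop("zone map and classification grid differ in dimensions")
  }
  ids <- as.integer(names(zones$zone_names))
  has_unzoned <- any(zones$zone_ids == 0L)
  all_ids <- c(ids, if (has_unzoned) 0L)
  counts <- vapply(all_ids, function(id) sum(map$mask[zones$zone_ids == id]),
                   numeric(1))
  data.frame(
    zone_id = all_ids,
    zone_name = c(unname(zones$zone_names[as.character(ids)]),
                  if (has_unzoned) "unzoned"),
    crop_year = if (is.null(map$crop_year_label)) NA_character_ else map$crop_year_label,
    pixel_count = as.integer(counts),
    soybean_area_ha = counts * pixel_area_ha,
    forecast_mode = map$mode,
    stringsAsFactors = FALSE
  )
}

#' Multi-year expansion map
#'
#' Per pixel, the index (1-based position in `maps`) of the earliest crop
#' year in which the pixel was classified soybean; 0 for pixels never
#' classified soybean. Appending further years can only turn 0s into
#' positive indices (monotone union).
#'
#' @param maps ordered list of `soybean_map` objects on one grid (earliest
#'   first).
#' @return integer matrix with attribute `crop_years` (the labels of
#'   `maps`).
#' @export
expansion_map <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "soybean_map")))
  dims <- dim(maps[[1]]$mask)
  out <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]$mask), dims)) stop("maps differ in grid dimensions")
    new <- out == 0L & maps[[i]]$mask
    out[new] <- i
  }
  attr(out, "crop_years") <-
    vapply(maps, function(m) m$crop_year_label %||% NA_character_, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total expanded area of an expansion map
#'
#' @param expansion integer matrix from [expansion_map()].
#' @param pixel_area_ha hectares per pixel.
#' @return hectares ever classified soybean (union over years).
#' @export
expansion_area_ha <- function(expansion, pixel_area_ha = 6.25) {
  sum(expansion > 0L) * pixel_area_ha
}

#' Stratified random sample of reference pixels
#'
#' Draws `n_per_class` pixels per class without replacement (the protocol
#' uses 200 soybean and 200 non-soybean reference pixels). Reproducible for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param reference data.frame with columns `row`, `col`, `class`.
#' @param n_per_class pixels to draw per class (default 200).
#' @param seed integer seed.
#' @param erode_border optional logical matrix (`TRUE` = interior); when
#'   supplied, reference pixels falling on `FALSE` cells are discarded
#'   before sampling, restricting the draw to field interiors.
#' @return data.frame, a subset of `reference` rows.
#' @export
stratified_sample <- function(reference, n_per_class = 200, seed,
                              erode_border = NULL) {
  stopifnot(is.data.frame(reference),
            all(c("row", "col", "class") %in% names(reference)))
  if (!is.null(erode_border)) {
    keep <- erode_border[cbind(reference$row, reference$col)]
    reference <- reference[keep, , drop = FALSE]
  }
  out <- with_seed(seed, {
    picked <- lapply(split(seq_len(nrow(reference)), reference$class), function(idx) {
      cls <- reference$class[idx[1]]
      if (length(idx) < n_per_class) {
        stop(sprintf("class '%s' has only %d reference pixels (< %d)",
                     cls, length(idx), n_per_class))
      }
      sample(idx, n_per_class)
    })
    reference[sort(unlist(picked)), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' 2 x 2 confusion matrix (classified x reference)
#'
#' Class order is fixed: soybean first, non-soybean second; rows are the
#' classified map, columns the reference.
#'
#' @param soy_soy,soy_non,non_soy,non_non the four cell counts: classified
#'   soybean / reference soybean, classified soybean / reference
#'   non-soybean, classified non-soybean / reference soybean, classified
#'   non-soybean / reference non-soybean. Alternatively pass a 2 x 2 matrix
#'   as `soy_soy`.
#' @return an object of class `confusion_matrix` (a 2 x 2 integer matrix).
#' @export
confusion_matrix <- function(soy_soy, soy_non = NULL, non_soy = NULL,
                             non_non = NULL) {
  m <- if (is.matrix(soy_soy)) {
    stopifnot(identical(dim(soy_soy), c(2L, 2L)))
    soy_soy
  } else {
    matrix(c(soy_soy, non_soy, soy_non, non_non), 2, 2)
  }
  if (any(m < 0)) stop("confusion-matrix counts must be non-negative")
  dimnames(m) <- list(classified = c("soybean", "non_soybean"),
                      reference = c("soybean", "non_soybean"))
  structure(m, class = c("confusion_matrix", class(matrix())))
}

#' Confusion matrix of a map against labelled reference pixels
#'
#' @param map a `soybean_map`.
#' @param sample data.frame with columns `row`, `col`, `class` where `class`
#'   is `"soybean"` or `"non_soybean"` (typically from
#'   [stratified_sample()]).
#' @return a [confusion_matrix()].
#' @export
confusion <- function(map, sample) {
  stopifnot(inherits(map, "soybean_map"),
            all(c("row", "col", "class") %in% names(sample)))
  classified <- ifelse(map$mask[cbind(sample$row, sample$col)],
                       "soybean", "non_soybean")
  reference <- as.character(sample$class)
  stopifnot(all(reference %in% c("soybean", "non_soybean")))
  lv <- c("soybean", "non_soybean")
  confusion_matrix(table(factor(classified, lv), factor(reference, lv)))
}

#' Accuracy metrics of a confusion matrix
#'
#' Overall accuracy is the diagonal fraction; user's accuracy of a class is
#' the diagonal over the classified-row total (commission side), producer's
#' accuracy the diagonal over the reference-column total (omission side).
#' Kappa is the chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_e` from the marginal products. Accuracies are reported in percent,
#' Kappa on its natural -1..1 scale.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `accuracy_report`: list with `overall`
#'   (percent), `users` and `producers` (named percent vectors), `kappa`,
#'   `n`.
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(
      overall = 100 * p_o,
      users = 100 * diag(m) / rowSums(m),
      producers = 100 * diag(m) / colSums(m),
      kappa = kappa,
      n = n
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.2f%% (n = %d), Kappa: %.3f\n",
              x$overall, x$n, x$kappa))
  cat(sprintf("  user's:     soybean %.2f%%, non-soybean %.2f%%\n",
              x$users["soybean"], x$users["non_soybean"]))
  cat(sprintf("  producer's: soybean %.2f%%, non-soybean %.2f%%\n",
              x$producers["soybean"], x$producers["non_soybean"]))
  invisible(x)
}

#' Regression diagnostics against official area statistics
#'
#' Ordinary least squares with the map-based estimate as predictor and the
#' official statistic as response (the map estimate "explains" the official
#' figure). RMSD is the root mean square deviation of the points about the
#' fitted line in the response direction; `fraction_within_2rmsd` is the
#' share of points within the double-RMSD band around the line. Set
#' `rmsd_about = "identity"` to measure deviations about the 1:1 line
#' instead.
#'
#' @param estimates numeric vector of map-based areas (ha), or a
#'   [zonal_area()]-style data.frame with `zone_id`, `crop_year`,
#'   `soybean_area_ha`.
#' @param official numeric vector of official areas (ha) paired with
#'   `estimates`, or a data.frame with `zone_id`, `crop_year`, `area_ha`
#'   merged on (zone, year).
#' @param rmsd_about `"fit"` (default) or `"identity"`.
#' @return an object of class `regression_report`: list with `slope`,
#'   `intercept_ha`, `r_squared`, `rmsd_ha`, `fraction_within_2rmsd`, `n`.
#' @export
regression_compare <- function(estimates, official, rmsd_about = c("fit", "identity")) {
  rmsd_about <- match.arg(rmsd_about)
  if (is.data.frame(estimates) || is.data.frame(official)) {
    stopifnot(is.data.frame(estimates), is.data.frame(official))
    merged <- merge(
      estimates[, c("zone_id", "crop_year", "soybean_area_ha")],
      official[, c("zone_id", "crop_year", "area_ha")],
      by = c("zone_id", "crop_year")
    )
    x <- merged$soybean_area_ha
    y <- merged$area_ha
  } else {
    stopifnot(length(estimates) == length(official))
    x <- as.numeric(estimates)
    y <- as.numeric(official)
  }
  if (length(x) < 3) stop("need at least three paired areas")
  fit <- stats::lm(y ~ x)
  resid <- if (rmsd_about == "fit") stats::residuals(fit) else y - x
  rmsd <- sqrt(mean(resid^2))
  frac <- if (rmsd == 0) 1 else mean(abs(resid) <= 2 * rmsd)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept_ha = unname(stats::coef(fit)[1]),
      r_squared = r2,
      rmsd_ha = rmsd,
      fraction_within_2rmsd = frac,
      n = length(x)
    ),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "Area regression (n = %d): official = %.3f x estimate + %.0f ha, R^2 = %.3f\n  RMSD = %.0f ha; %.1f%% of points within the double-RMSD band\n",
    x$n, x$slope, x$intercept_ha, x$r_squared, x$rmsd_ha,
    100 * x$fraction_within_2rmsd
  ))
  invisible(x)
}

#' Field-campaign summary arithmetic
#'
#' Converts a campaign's total mapped area and field count into the mean
#' field area and the equivalent (truncated) count of 250 m pixels.
#'
#' @param total_area_ha total mapped area in hectares.
#' @param n_fields number of fields.
#' @param pixel_area_ha hectares per pixel (default 6.25).
#' @return list with `mean_field_area_ha` and `pixel_count`.
#' @export
field_campaign_summary <- function(total_area_ha, n_fields, pixel_area_ha = 6.25) {
  stopifnot(total_area_ha >= 0, n_fields >= 1, pixel_area_ha > 0)
  list(
    mean_field_area_ha = total_area_ha / n_fields,
    pixel_count = as.integer(floor(total_area_ha / pixel_area_ha))
  )
}
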