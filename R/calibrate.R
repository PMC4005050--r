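# Estimation of Lmin / Umin / Amp from paired min/max EVI samples, and the
# fixed-parameter discipline across crop years.

#' Paired MinMean / MaxMean EVI calibration sample
#'
#' Calibration sites are nominally 100 x 100 pixel windows; `min_values` and
#' `max_values` are the paired per-pixel MinMeanEVI and MaxMeanEVI samples
#' drawn from them.
#'
#' @param min_values,max_values paired numeric vectors of equal length.
#' @param site_id site identifier.
#' @param crop_year_label optional crop-year label.
#' @return an object of class `calibration_sample`.
#' @export
calibration_sample <- function(min_values, max_values, site_id = "site",
                               crop_year_label = NULL) {
  stopifnot(length(min_values) == length(max_values))
  keep <- !(is.na(min_values) | is.na(max_values))
  structure(
    list(min_values = as.numeric(min_values[keep]),
         max_values = as.numeric(max_values[keep]),
         site_id = site_id, crop_year_label = crop_year_label),
    class = "calibration_sample"
  )
}

pool_samples <- function(samples) {
  if (inherits(samples, "calibration_sample")) samples <- list(samples)
  stopifnot(all(vapply(samples, inherits, logical(1), "calibration_sample")))
  list(
    mn = unlist(lapply(samples, `[[`, "min_values")),
    mx = unlist(lapply(samples, `[[`, "max_values"))
  )
}

#' Estimate Lmin from the MinMeanEVI distribution
#'
#' Lmin separates crop pixels from the cloud-shadow / water mode at the
#' bottom of the minimum image. The water/shadow mode (values below
#' `exclude_below`) is dropped and a low quantile of the remainder is
#' returned.
#'
#' @param samples one or a list of [calibration_sample()] objects.
#' @param probs quantile of the retained minimum values (default 0.01).
#' @param exclude_below drop values below this (default 0, the water/shadow
#'   mode).
#' @return Lmin estimate (EVI units).
#' @export
estimate_lmin <- function(samples, probs = 0.01, exclude_below = 0) {
  p <- pool_samples(samples)
  x <- p$mn[p$mn >= exclude_below]
  if (length(x) == 0) stop("no minimum values remain after excluding the water/shadow mode")
  unname(stats::quantile(x, probs))
}

#' Estimate Umin from min/max scatter convergence
#'
#' Umin is the MinMeanEVI value at which the minimum and maximum mean EVI
#' images converge: above it, pixels keep a high EVI year-round (natural
#' vegetation) and their min and max values collapse onto the scatterplot
#' diagonal. Operationally the paired (min, max) values are binned into
#' columns of width `bin_width` along the min axis; scanning upward from
#' `lmin`, Umin is the centre of the first column in which the fraction of
#' mass within the diagonal band `|max - min| < band_width` exceeds
#' `density_frac`. Deterministic, order-invariant and invariant under
#' duplicating the sample.
#'
#' @param samples one or a list of [calibration_sample()] objects.
#' @param bin_width histogram column width on the min axis (EVI units).
#' @param band_width half-width of the diagonal convergence band.
#' @param density_frac column-mass fraction that must lie in the band.
#' @param lmin lower bound of the scan.
#' @param min_n below this many pairs a low-confidence warning is raised.
#' @return Umin estimate (EVI units), with attribute `low_confidence` when
#'   the sample is small and `converged = FALSE` plus a 0.99 min-quantile
#'   fallback when no convergent column exists.
#' @export
estimate_umin <- function(samples, bin_width = 0.01, band_width = 0.05,
                          density_frac = 0.05, lmin = 0.05, min_n = 1000) {
  p <- pool_samples(samples)
  low_conf <- FALSE
  if (length(p$mn) < min_n) {
    warning(sprintf("insufficient calibration data (%d pairs < %d); Umin estimate is low-confidence",
                    length(p$mn), min_n))
    low_conf <- TRUE
  }
  keep <- p$mn >= lmin
  mn <- p$mn[keep]; mx <- p$mx[keep]
  if (length(mn)) {
    col <- floor((mn - lmin) / bin_width)
    in_band <- abs(mx - mn) < band_width
    mass <- tapply(rep(1, length(col)), col, sum)
    band_mass <- tapply(as.numeric(in_band), col, sum)
    frac <- band_mass / mass
    hit <- names(frac)[frac > density_frac]
    if (length(hit)) {
      u <- lmin + (min(as.numeric(hit)) + 0.5) * bin_width
      return(structure(u, low_confidence = low_conf, converged = TRUE))
    }
  }
  warning("no convergence between min and max EVI distributions; returning the 0.99 min-quantile")
  structure(unname(stats::quantile(p$mn, 0.99)),
            low_confidence = low_conf, converged = FALSE)
}

#' Estimate Amp from the crop cluster's amplitude distribution
#'
#' Amp is the smallest max-minus-min difference at which a mixed soybean
#' pixel (field border) is still designated soybean. Among pixels whose
#' minimum lies at or below `umin` (the annual-crop side of the scatter),
#' amplitudes inside the diagonal convergence band (`< band_width`) are
#' discarded and a low quantile of the remaining crop-cluster amplitudes is
#' returned.
#'
#' @param samples one or a list of [calibration_sample()] objects.
#' @param umin upper MinMean bound delimiting the crop side of the scatter.
#' @param band_width diagonal band excluded as converged (non-crop) mass.
#' @param probs quantile of the retained amplitudes (default 0.01).
#' @return Amp estimate (EVI units); on a degenerate sample with no
#'   amplitude mass beyond the band, a warning plus the quantile over all
#'   amplitudes on the crop side.
#' @export
estimate_amp <- function(samples, umin = 0.39, band_width = 0.05, probs = 0.01) {
  p <- pool_samples(samples)
  amp <- p$mx - p$mn
  crop_side <- p$mn <= umin
  a <- amp[crop_side & amp >= band_width]
  if (length(a) == 0) {
    warning("degenerate sample: no amplitude mass beyond the convergence band; falling back to the crop-side quantile")
    a <- amp[crop_side]
    if (length(a) == 0) stop("no samples on the crop side of the scatter")
  }
  unname(stats::quantile(a, probs))
}

#' Freeze one parameter set across all crop years
#'
#' The thresholds are physically driven and, once identified, are applied to
#' every crop year alike; they are not re-tuned per year. Per-year estimates
#' are collapsed to their medians (or overridden by pinned values, e.g. the
#' operational set 0.05/0.39/0.36) and validated; the per-year estimates are
#' retained as an attribute for audit.
#'
#' @param estimates data.frame with columns `lmin`, `umin`, `amp` (one row
#'   per crop year; an optional `crop_year` column is kept for audit).
#' @param pinned optional named list/vector overriding any of `lmin`,
#'   `umin`, `amp`.
#' @param slope_threshold_pct percent-slope limit carried into the set.
#' @return an [mcda_parameters()] object with attribute
#'   `per_year_estimates`.
#' @export
freeze_parameters <- function(estimates, pinned = NULL,
                              slope_threshold_pct = 12) {
  stopifnot(is.data.frame(estimates),
            all(c("lmin", "umin", "amp") %in% names(estimates)))
  val <- list(
    lmin = stats::median(estimates$lmin),
    umin = stats::median(estimates$umin),
    amp = stats::median(estimates$amp)
  )
  for (k in names(pinned)) {
    if (!k %in% names(val)) stop(sprintf("unknown pinned parameter '%s'", k))
    val[[k]] <- as.numeric(pinned[[k]])
  }
  out <- mcda_parameters(lmin = val$lmin, umin = val$umin, amp = val$amp,
                         slope_threshold_pct = slope_threshold_pct)
  attr(out, "per_year_estimates") <- estimates
  out
}
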