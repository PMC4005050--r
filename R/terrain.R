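# Percent slope from a DEM and the mechanization mask (condition C).

#' Digital elevation model raster
#'
#' @param elevation numeric matrix of elevations in metres (`NA` = nodata).
#' @param cell_size_m ground sampling distance in metres (90 for SRTM-derived
#'   slope products).
#' @return an object of class `dem_raster`.
#' @export
dem_raster <- function(elevation, cell_size_m) {
  stopifnot(is.matrix(elevation), is.numeric(elevation), cell_size_m > 0)
  v <- elevation[!is.na(elevation)]
  if (length(v) && (min(v) < -500 || max(v) > 9000)) {
    stop("elevations outside plausible bounds (-500..9000 m)")
  }
  structure(list(elevation = elevation, cell_size_m = cell_size_m),
            class = "dem_raster")
}

# pad a matrix by one linearly extrapolated row/column on each side, so the
# 3x3 stencil reduces to one-sided differences at the border
pad_extrapolate <- function(z) {
  n <- nrow(z); m <- ncol(z)
  z2 <- rbind(2 * z[1, ] - z[2, ], z, 2 * z[n, ] - z[n - 1, ])
  cbind(2 * z2[, 1] - z2[, 2], z2, 2 * z2[, m] - z2[, m - 1])
}

#' Percent slope of a DEM (Horn's method)
#'
#' East-west and north-south gradients from Horn's 3x3 weighted central
#' differences; border pixels use one-sided differences (via linear
#' extrapolation of the border). Slope is `100 * sqrt(gx^2 + gy^2)`, so a
#' 45-degree ramp is 100%. Nodata propagates to every pixel whose stencil
#' touches it. Invariant under adding a constant to all elevations.
#'
#' @param dem a [dem_raster()] of at least 3 x 3 cells.
#' @return numeric matrix of percent slope.
#' @export
slope_percent <- function(dem) {
  stopifnot(inherits(dem, "dem_raster"))
  z <- dem$elevation
  n <- nrow(z); m <- ncol(z)
  if (n < 3 || m < 3) stop("slope requires a grid of at least 3 x 3 cells")
  p <- pad_extrapolate(z)
  sh <- function(dr, dc) p[(1 + dr):(n + dr), (1 + dc):(m + dc)]
  h <- dem$cell_size_m
  # Horn weights: corners 1, edge neighbours 2
  gx <- ((sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
           (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))) / (8 * h)
  gy <- ((sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
           (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))) / (8 * h)
  100 * sqrt(gx^2 + gy^2)
}

#' Mechanization mask (condition C)
#'
#' Soybean in the study system is a highly mechanized crop; pixels steeper
#' than the threshold are excluded. The exclusion is strictly "slope >
#' threshold": a pixel at exactly 12% remains mechanizable.
#'
#' @param slope numeric matrix of percent slope.
#' @param threshold_pct percent-slope limit (default 12).
#' @return logical matrix, `TRUE` = mechanizable; `FALSE` on nodata.
#' @export
mechanization_mask <- function(slope, threshold_pct = 12) {
  stopifnot(is.matrix(slope))
  m <- slope <= threshold_pct
  m[is.na(m)] <- FALSE
  m
}

#' Aggregate a fine-resolution boolean mask to a coarser grid
#'
#' Reconciles the 90 m slope-mask grid with the 250 m composite grid: each
#' target pixel is `TRUE` iff at least `majority` of the fine cells mapping
#' into it are `TRUE`. Cell centres are assigned by proportional index
#' scaling, which reduces to nearest-neighbour when the grids align.
#'
#' @param mask logical matrix at the fine resolution.
#' @param target_dim integer `c(rows, cols)` of the target grid.
#' @param majority required fraction of `TRUE` fine cells (default 0.5,
#'   compared with `>=`).
#' @return logical matrix of dimension `target_dim`.
#' @export
resample_mask_to_grid <- function(mask, target_dim, majority = 0.5) {
  stopifnot(is.matrix(mask), is.logical(mask), length(target_dim) == 2)
  rs <- nrow(mask); cs <- ncol(mask)
  rt <- as.integer(target_dim[1]); ct <- as.integer(target_dim[2])
  ri <- pmin(rt, floor((seq_len(rs) - 0.5) * rt / rs) + 1L)
  ci <- pmin(ct, floor((seq_len(cs) - 0.5) * ct / cs) + 1L)
  tgt_row <- ri[row(mask)]
  tgt_col <- ci[col(mask)]
  idx <- (tgt_col - 1L) * rt + tgt_row
  frac_true <- tapply(as.numeric(mask), idx, mean)
  out <- matrix(FALSE, rt, ct)
  out[as.integer(names(frac_true))] <- frac_true >= majority
  out
}
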