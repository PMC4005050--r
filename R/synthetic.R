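# Synthetic scenes: land-cover phenology profiles, rendered composite
# stacks, DEM, zone map, rainfall and ground truth, so the whole pipeline is
# testable without any satellite data.

#' Land-cover class specification for the scene generator
#'
#' Phenology is a double-logistic seasonal EVI curve: green-up rises from
#' `base_evi` after `sowing_doy` towards `peak_evi` around `peak_doy`, and
#' senescence brings it back down `season_length_days` after sowing. The
#' curve is periodic over the 365-day calendar, so prior and following crop
#' years behave identically (stationary phenology). Double-cropping classes
#' superpose a second calendar-shifted curve for the succeeding crop.
#'
#' @param class_name one of `soybean_single`, `soybean_cotton`,
#'   `soybean_maize`, `cotton_single`, `cerrado`, `forest`, `water`.
#' @param base_evi,peak_evi off-season and peak EVI (0 <= base < peak <= 1).
#' @param sowing_doy,peak_doy,season_length_days calendar of the (first)
#'   crop: sowing day-of-year, day-of-year of full canopy, and days from
#'   sowing to the senescence midpoint.
#' @param noise_sd per-composite additive Gaussian noise (EVI units).
#' @param fraction share of the scene covered by the class.
#' @param second optional list (`base to peak via `peak_evi`, `sowing_doy`,
#'   `peak_doy`, `season_length_days`) describing the succeeding crop of a
#'   double-cropping system.
#' @return an object of class `land_cover_spec`.
#' @export
land_cover_spec <- function(class_name, base_evi, peak_evi, sowing_doy,
                            peak_doy, season_length_days, noise_sd = 0.02,
                            fraction, second = NULL) {
  if (!(base_evi >= 0 && base_evi < peak_evi && peak_evi <= 1)) {
    stop("need 0 <= base_evi < peak_evi <= 1")
  }
  structure(
    list(class_name = class_name, base_evi = base_evi, peak_evi = peak_evi,
         sowing_doy = sowing_doy, peak_doy = peak_doy,
         season_length_days = season_length_days,
         noise_sd = noise_sd, fraction = fraction, second = second),
    class = "land_cover_spec"
  )
}

# seasonal double-logistic, evaluated at day-of-year (periodic over 365).
# Shape constants (midpoint at 72% of the green-up, rates tied to the
# green-up length and season length) are fixed curve-family choices.
season_curve <- function(doy, sowing_doy, peak_doy, season_length) {
  t_rel <- (doy - sowing_doy) %% 365
  rise_len <- (peak_doy - sowing_doy) %% 365
  m1 <- 0.72 * rise_len
  r1 <- rise_len / 11.4
  m2 <- season_length
  r2 <- season_length / 9.6
  stats::plogis((t_rel - m1) / r1) * stats::plogis((m2 - t_rel) / r2)
}

#' Noise-free seasonal EVI value of a class
#'
#' @param spec a [land_cover_spec()].
#' @param doy day-of-year vector.
#' @return numeric vector of EVI values (no noise, not clipped).
#' @export
evi_curve <- function(spec, doy) {
  v <- spec$base_evi + (spec$peak_evi - spec$base_evi) *
    season_curve(doy, spec$sowing_doy, spec$peak_doy, spec$season_length_days)
  if (!is.null(spec$second)) {
    s <- spec$second
    v <- v + (s$peak_evi - spec$base_evi) *
      season_curve(doy, s$sowing_doy, s$peak_doy, s$season_length_days)
  }
  v
}

#' Sample a class's EVI profile at composite dates
#'
#' Evaluates the class curve at each (year, doy) and adds per-date Gaussian
#' noise, clipped to the physical EVI range [-0.2, 1]. With `noise_sd = 0`
#' the profile is deterministic.
#'
#' @param spec a [land_cover_spec()].
#' @param dates data.frame with columns `year` and `doy`.
#' @param seed integer seed for the noise draw.
#' @return numeric vector, one EVI value per row of `dates`.
#' @export
evi_profile <- function(spec, dates, seed = 1) {
  stopifnot(all(c("year", "doy") %in% names(dates)))
  v <- evi_curve(spec, dates$doy)
  if (spec$noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, spec$noise_sd))
  }
  pmin(pmax(v, -0.2), 1)
}

#' Default land-cover class mix
#'
#' Seven classes with the phenological structure the classifier assumes:
#' annual soybean with a low sowing-window trough and a high December to
#' February peak; double-cropping variants with cotton (peak around June) or
#' maize after the soybean harvest; December-sown cotton that peaks after
#' the soybean peak window; cerrado savanna and forest with persistently
#' high minimum EVI; and near-zero water. Class fractions sum to 1.
#'
#' @param cotton_shift_days calendar shift (days) applied to the
#'   soybean-cotton double-cropping class. A +30-day shift emulates
#'   producers delaying soybean to leave room for a long cotton cycle,
#'   detuning the peak window and depressing the observed amplitude below
#'   `Amp` - the documented double-cropping omission mechanism.
#' @param noise_sd per-composite noise for all vegetated classes (water
#'   uses half).
#' @return named list of [land_cover_spec()] objects.
#' @export
default_land_cover_specs <- function(cotton_shift_days = 0, noise_sd = 0.02) {
  soy <- list(sowing_doy = 289, peak_doy = 4, season_length_days = 115)
  specs <- list(
    soybean_single = land_cover_spec(
      "soybean_single", 0.18, 0.85, soy$sowing_doy, soy$peak_doy,
      soy$season_length_days, noise_sd, fraction = 0.30
    ),
    soybean_cotton = land_cover_spec(
      "soybean_cotton", 0.18, 0.85,
      (soy$sowing_doy + cotton_shift_days - 1) %% 365 + 1,
      (soy$peak_doy + cotton_shift_days - 1) %% 365 + 1,
      soy$season_length_days, noise_sd, fraction = 0.15,
      second = list(peak_evi = 0.80,
                    sowing_doy = (70 + cotton_shift_days - 1) %% 365 + 1,
                    peak_doy = (160 + cotton_shift_days - 1) %% 365 + 1,
                    season_length_days = 130)
    ),
    soybean_maize = land_cover_spec(
      "soybean_maize", 0.18, 0.85, soy$sowing_doy, soy$peak_doy,
      soy$season_length_days, noise_sd, fraction = 0.10,
      second = list(peak_evi = 0.75, sowing_doy = 75, peak_doy = 150,
                    season_length_days = 110)
    ),
    cotton_single = land_cover_spec(
      "cotton_single", 0.15, 0.80, 345, 100, 180, noise_sd, fraction = 0.10
    ),
    cerrado = land_cover_spec(
      "cerrado", 0.48, 0.65, 274, 30, 240, noise_sd, fraction = 0.20
    ),
    forest = land_cover_spec(
      "forest", 0.55, 0.75, 250, 20, 300, noise_sd, fraction = 0.10
    ),
    water = land_cover_spec(
      "water", 0.01, 0.03, 289, 4, 115, noise_sd / 2, fraction = 0.05
    )
  )
  specs
}

soybean_classes <- c("soybean_single", "soybean_cotton", "soybean_maize")

# tile the grid into rectangular fields; returns an integer field-id matrix
tile_fields <- function(nr, nc, side_px) {
  sides <- pmax(3L, side_px + (-1:2)) # small jitter around the target side
  heights <- integer(0)
  while (sum(heights) < nr) heights <- c(heights, sample(sides, 1))
  heights[length(heights)] <- nr - sum(heights[-length(heights)])
  field_id <- matrix(0L, nr, nc)
  next_id <- 1L
  r0 <- 0L
  for (h in heights) {
    widths <- integer(0)
    while (sum(widths) < nc) widths <- c(widths, sample(sides, 1))
    widths[length(widths)] <- nc - sum(widths[-length(widths)])
    c0 <- 0L
    for (w in widths) {
      field_id[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- next_id
      next_id <- next_id + 1L
      c0 <- c0 + w
    }
    r0 <- r0 + h
  }
  field_id
}

# first 4-neighbour (N, S, W, E precedence) belonging to a different field;
# 0 where the pixel is interior to its field
neighbour_field <- function(field_id) {
  nr <- nrow(field_id); nc <- ncol(field_id)
  out <- matrix(0L, nr, nc)
  shifts <- list(
    rbind(field_id[1, ], field_id[-nr, ]),         # north neighbour
    rbind(field_id[-1, ], field_id[nr, ]),         # south
    cbind(field_id[, 1], field_id[, -nc]),         # west
    cbind(field_id[, -1], field_id[, nc])          # east
  )
  for (s in shifts) {
    take <- out == 0L & s != field_id
    out[take] <- s[take]
  }
  out
}

#' Generate a complete synthetic scene
#'
#' Tiles the grid into rectangular fields (side drawn around
#' `sqrt(field_size_ha / pixel_area_ha)` pixels, default matching a mean
#' field of about 183 ha at 6.25 ha/pixel), assigns each field a class by
#' the spec fractions, and renders the 16-day composites needed for both
#' forecast modes of `crop_year`: the sowing and maximum-development windows
#' of the crop year itself and of the prior crop year. A 1-pixel boundary
#' band between unlike fields carries 50/50 area-weighted mixed profiles.
#' The DEM (on the same grid) is flat except a steep stripe exceeding the
#' 12% mechanization limit; zones split the grid into quadrant
#' "municipalities". Fully reproducible from `seed`; the caller's RNG state
#' is untouched.
#'
#' @param specs named list of [land_cover_spec()] (fractions summing to 1).
#' @param dim grid size `c(rows, cols)`.
#' @param crop_year starting calendar year of the target crop year.
#' @param field_size_ha mean field area in hectares.
#' @param pixel_area_ha hectares per pixel.
#' @param steep_frac fraction of rows covered by the steep stripe (0 to
#'   disable).
#' @param seed integer seed.
#' @return list with `series` ([composite_series()]), `truth` (list:
#'   `class_grid` character matrix, `soybean_mask`, `interior_mask` - pixels
#'   away from field borders -, `field_id`), `dem` ([dem_raster()]),
#'   `zones` ([zone_map()]), and `steep_mask` (logical, `TRUE` on the steep
#'   stripe).
#' @export
generate_scene <- function(specs = default_land_cover_specs(),
                           dim = c(200, 200), crop_year = 2006,
                           field_size_ha = 182.7, pixel_area_ha = 6.25,
                           steep_frac = 0.05, seed = 1) {
  fr <- vapply(specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("class fractions must sum to 1")
  nr <- as.integer(dim[1]); nc <- as.integer(dim[2])
  with_seed(seed, {
    side_px <- as.integer(round(sqrt(field_size_ha / pixel_area_ha)))
    field_id <- tile_fields(nr, nc, side_px)
    n_fields <- max(field_id)
    field_class <- sample(names(specs), n_fields, replace = TRUE, prob = fr)
    class_grid <- matrix(field_class[field_id], nr, nc)
    nb_field <- neighbour_field(field_id)
    border <- nb_field != 0L &
      matrix(field_class[pmax(nb_field, 1L)], nr, nc) != class_grid
    # composite dates: sowing + maxdev windows of crop years Y-1 and Y
    dates <- unique(rbind(
      expand.grid(year = crop_year - 1, doy = seq(225L, 353L, 16L)),
      expand.grid(year = crop_year, doy = c(1L, 17L, 33L)),
      expand.grid(year = crop_year, doy = seq(225L, 353L, 16L)),
      expand.grid(year = crop_year + 1, doy = c(1L, 17L, 33L))
    ))
    dates <- dates[order(dates$year, dates$doy), ]
    curves <- vapply(specs, evi_curve, numeric(nrow(dates)), doy = dates$doy)
    noise_sd_px <- matrix(
      vapply(specs, `[[`, numeric(1), "noise_sd")[class_grid], nr, nc)
    composites <- vector("list", nrow(dates))
    cls_idx <- matrix(match(class_grid, names(specs)), nr, nc)
    nb_idx <- matrix(match(field_class[pmax(nb_field, 1L)], names(specs)), nr, nc)
    for (k in seq_len(nrow(dates))) {
      v <- matrix(curves[k, cls_idx], nr, nc)
      v[border] <- (v[border] + curves[k, nb_idx[border]]) / 2
      v <- v + stats::rnorm(nr * nc, 0, noise_sd_px)
      v <- pmin(pmax(v, -0.2), 1)
      composites[[k]] <- evi_composite(v, dates$year[k], dates$doy[k],
                                       scale_factor = 1)
    }
    series <- composite_series(composites, pixel_area_ha = pixel_area_ha)
    # DEM: flat plain with one cross-slope stripe above the 12% limit
    cell_m <- sqrt(pixel_area_ha * 1e4)
    elev <- matrix(400, nr, nc)
    steep_mask <- matrix(FALSE, nr, nc)
    n_steep <- round(steep_frac * nr)
    if (n_steep > 0) {
      r0 <- max(1L, as.integer(round(nr * 0.45)))
      rows <- r0:min(nr, r0 + n_steep - 1L)
      elev[rows, ] <- 400 + 0.25 * cell_m * (seq_along(rows) - 1) # 25% slope
      steep_mask[rows, ] <- TRUE
    }
    dem <- dem_raster(elev, cell_size_m = cell_m)
    # quadrant municipalities
    zones <- zone_map(
      outer(seq_len(nr) > nr / 2, seq_len(nc) > nc / 2,
            function(a, b) 1L + a + 2L * b),
      stats::setNames(sprintf("municipality_%d", 1:4), 1:4)
    )
    list(
      series = series,
      truth = list(
        class_grid = class_grid,
        soybean_mask = matrix(class_grid %in% soybean_classes, nr, nc),
        interior_mask = !border,
        field_id = field_id
      ),
      dem = dem,
      zones = zones,
      steep_mask = steep_mask
    )
  })
}

#' Generate a dekadal rainfall series
#'
#' Dekadal (10-day) accumulations from 1 September through late March.
#' With `deficit = FALSE` every record exceeds the 10 mm event threshold, so
#' no 30-day span is dry; with `deficit = TRUE` four consecutive dekads in
#' November-December are capped below 10 mm, embedding a dry spell longer
#' than 30 days.
#'
#' @param deficit embed a water deficit.
#' @param seed integer seed.
#' @param year calendar year of the 1 September season start.
#' @param station_id station identifier.
#' @return a [rainfall_series()].
#' @export
generate_rainfall <- function(deficit = FALSE, seed = 1, year = 2006,
                              station_id = "synthetic") {
  start <- as.Date(sprintf("%d-09-01", year))
  dates <- seq(start, by = 10, length.out = 21)
  with_seed(seed, {
    accum <- stats::runif(21, 12, 80)
    if (deficit) accum[7:10] <- stats::runif(4, 0, 8)
    rainfall_series(dates, accum, station_id = station_id)
  })
}
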