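# Raster and table I/O. Rasters use the ESRI ASCII grid interchange format
# (plain text, nodata-aware); (year, doy) tags travel in filenames matching
# `<prefix>_<year>_<doy>.asc` or in a manifest CSV for opaque names.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix (`NA` = nodata).
#' @param path output file path (conventionally `.asc`).
#' @param cellsize cell size in map units (metres).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata nodata sentinel written to the file.
#' @param digits significant digits for the values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, cellsize = 250,
                             xllcorner = 0, yllcorner = 0,
                             nodata = -9999, digits = 6) {
  stopifnot(is.matrix(values))
  header <- c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.6f", xllcorner),
    sprintf("yllcorner %.6f", yllcorner),
    sprintf("cellsize %.6f", cellsize),
    sprintf("NODATA_value %s", format(nodata))
  )
  v <- signif(values, digits)
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return numeric matrix (`NA` = nodata) with attributes `cellsize`,
#'   `xllcorner`, `yllcorner`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows")) {
    if (is.null(hdr[[k]])) stop(sprintf("malformed ASCII grid: missing %s", k))
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid value count does not match header")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(m,
            cellsize = hdr$cellsize %||% NA_real_,
            xllcorner = hdr$xllcorner %||% NA_real_,
            yllcorner = hdr$yllcorner %||% NA_real_)
}

#' Write a composite series as one ASCII grid per composite
#'
#' Files are named `<prefix>_<year>_<doy>.asc` (doy zero-padded to three
#' digits), the pattern [read_composite_stack()] parses back.
#'
#' @param series a [composite_series()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param cellsize cell size in metres.
#' @return character vector of written paths, invisibly.
#' @export
write_composite_series <- function(series, dir, prefix = "evi", cellsize = 250) {
  stopifnot(inherits(series, "composite_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(series$composites, function(cc) {
    p <- file.path(dir, sprintf("%s_%d_%03d.asc", prefix, cc$year, cc$doy))
    write_ascii_grid(cc$values, p, cellsize = cellsize)
    p
  }, character(1))
  invisible(paths)
}

#' Read a stack of composite rasters into a series
#'
#' Either scans `path` for files matching `<prefix>_<year>_<doy>.asc` or
#' follows a manifest CSV with columns `file`, `year`, `doy` (paths relative
#' to the manifest). Integer-scaled EVI (the 1e-4 convention) is
#' auto-detected per file; grids must agree, duplicate tags are an error.
#'
#' @param path directory of `.asc` files, ignored when `manifest` is given.
#' @param manifest optional manifest CSV path.
#' @param prefix filename prefix for directory scanning.
#' @param pixel_area_ha hectares per pixel for the resulting series.
#' @param scale_factor forced scale factor (`NULL` = auto-detect).
#' @return a [composite_series()].
#' @export
read_composite_stack <- function(path = NULL, manifest = NULL, prefix = "evi",
                                 pixel_area_ha = 6.25, scale_factor = NULL) {
  if (!is.null(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("file", "year", "doy") %in% names(tab)))
    files <- file.path(dirname(manifest), tab$file)
    years <- as.integer(tab$year)
    doys <- as.integer(tab$doy)
  } else {
    pat <- sprintf("^%s_(\\d{4})_(\\d{1,3})\\.asc$", prefix)
    files <- list.files(path, pattern = pat, full.names = TRUE)
    if (length(files) == 0) stop(sprintf("no composite files matching '%s' in %s", pat, path))
    mm <- regmatches(basename(files), regexec(pat, basename(files)))
    years <- vapply(mm, function(m) as.integer(m[2]), integer(1))
    doys <- vapply(mm, function(m) as.integer(m[3]), integer(1))
  }
  comps <- lapply(seq_along(files), function(i) {
    evi_composite(unclass(read_ascii_grid(files[i]))[, , drop = FALSE],
                  years[i], doys[i], scale_factor = scale_factor)
  })
  composite_series(comps, pixel_area_ha = pixel_area_ha)
}

#' Write a soybean map raster with a JSON provenance sidecar
#'
#' The raster encodes 1 = soybean, 0 = other, nodata for masked pixels; the
#' sidecar (`<path>.json`) records the forecast mode, parameters, fallback
#' flag and source composite tags.
#'
#' @param map a `soybean_map`.
#' @param path output `.asc` path.
#' @param cellsize cell size in metres.
#' @return `path`, invisibly.
#' @export
write_soybean_map <- function(map, path, cellsize = 250) {
  stopifnot(inherits(map, "soybean_map"))
  v <- matrix(as.numeric(map$mask), nrow(map$mask), ncol(map$mask))
  v[map$nodata] <- NA
  write_ascii_grid(v, path, cellsize = cellsize, nodata = 255, digits = 1)
  side <- list(
    crop_year = map$crop_year_label,
    forecast_mode = map$mode,
    fallback_used = map$fallback_used,
    parameters = map$params[c("lmin", "umin", "amp", "slope_threshold_pct",
                              "strict_inequalities")],
    source_tags = map$source_tags
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}

#' Read a soybean map raster written by [write_soybean_map()]
#'
#' @param path `.asc` path; the `.json` sidecar is read when present.
#' @return a `soybean_map`.
#' @export
read_soybean_map <- function(path) {
  v <- read_ascii_grid(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path)
  params <- if (!is.null(side$parameters)) {
    do.call(mcda_parameters, side$parameters)
  } else {
    mcda_parameters()
  }
  structure(
    list(
      mask = !is.na(v) & v == 1,
      nodata = is.na(unclass(v))[, , drop = FALSE],
      mode = side$forecast_mode %||% "second",
      fallback_used = isTRUE(side$fallback_used),
      crop_year_label = side$crop_year,
      params = params,
      conditions = NULL,
      source_tags = NULL
    ),
    class = "soybean_map"
  )
}

#' Write an area table as CSV
#'
#' Fixed column order `zone_id, zone_name, crop_year, pixel_count,
#' soybean_area_ha, forecast_mode`; byte-identical on rerun.
#'
#' @param table a [zonal_area()] data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(table, path) {
  cols <- c("zone_id", "zone_name", "crop_year", "pixel_count",
            "soybean_area_ha", "forecast_mode")
  stopifnot(all(cols %in% names(table)))
  out <- table[, cols]
  out$soybean_area_ha <- signif(out$soybean_area_ha, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metrics report (confusion matrix, accuracy, regression) as JSON
#'
#' @param x an `accuracy_report`, `regression_report` or
#'   [confusion_matrix()] (the latter is written as counts plus derived
#'   metrics).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  obj <- if (inherits(x, "confusion_matrix")) {
    rep <- accuracy_metrics(x)
    list(counts = unclass(x), metrics = unclass(rep))
  } else {
    unclass(x)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}

#' Read / write threshold parameters as a flat YAML file
#'
#' Keys: `lmin`, `umin`, `amp`, `slope_threshold_pct`,
#' `strict_inequalities`.
#'
#' @param path YAML file path.
#' @return [read_params_file()]: an [mcda_parameters()] object.
#' @export
read_params_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("lmin", "umin", "amp", "slope_threshold_pct", "strict_inequalities")
  do.call(mcda_parameters, cfg[intersect(names(cfg), known)])
}

#' @rdname read_params_file
#' @param params an [mcda_parameters()] object.
#' @export
write_params_file <- function(params, path) {
  stopifnot(inherits(params, "mcda_parameters"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
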