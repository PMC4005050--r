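# Dekadal (10-day accumulated) station rainfall: water-deficit detection and
# the advisory sowing-onset date.

#' Station rainfall series of 10-day accumulated precipitation
#'
#' @param dates Date vector of record dates (strictly increasing); each
#'   record is the precipitation accumulated over the 10 days ending on its
#'   date.
#' @param accum_mm non-negative accumulations in millimetres.
#' @param station_id station identifier.
#' @return a data.frame of class `rainfall_series` with columns `date` and
#'   `accum_mm` and attribute `station_id`.
#' @export
rainfall_series <- function(dates, accum_mm, station_id = "station") {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(accum_mm), length(dates) >= 1)
  if (any(diff(as.numeric(dates)) <= 0)) stop("dates must be strictly increasing")
  if (any(accum_mm < 0)) stop("accumulations must be non-negative")
  structure(
    data.frame(date = dates, accum_mm = as.numeric(accum_mm)),
    station_id = station_id,
    class = c("rainfall_series", "data.frame")
  )
}

#' Detect a 30-day water deficit
#'
#' `TRUE` iff the window contains a span of at least 30 consecutive days with
#' no rainfall event, where an event is a 10-day accumulation record
#' exceeding `event_mm` (10 mm). The classifier uses this to substitute
#' prior-year peak images when the current growing season failed. The check
#' is applied per supplied series; with several stations, callers decide the
#' zone of influence (the package applies one series scene-wide).
#'
#' @param rain a [rainfall_series()].
#' @param start,end window bounds (Date); default the full record span.
#' @param event_mm rainfall-event threshold in millimetres.
#' @return logical scalar.
#' @export
water_deficit <- function(rain, start = NULL, end = NULL, event_mm = 10) {
  stopifnot(inherits(rain, "rainfall_series"))
  if (nrow(rain) == 0) stop("empty rainfall series")
  if (is.null(start)) start <- min(rain$date)
  if (is.null(end)) end <- max(rain$date)
  in_win <- rain$date >= start & rain$date <= end
  events <- as.numeric(rain$date[in_win & rain$accum_mm > event_mm])
  s <- as.numeric(as.Date(start))
  e <- as.numeric(as.Date(end))
  if (length(events) == 0) return((e - s + 1) >= 30)
  # dry spans: before the first event, between events, after the last event
  gaps <- c(events[1] - s, diff(events) - 1, e - events[length(events)])
  any(gaps >= 30)
}

#' Advisory sowing-onset date from rainfall
#'
#' First dekadal record at or after 1 September whose accumulation reaches
#' `threshold_mm`. Informational metadata only: the classification windows
#' stay fixed at their DOY defaults unless explicitly overridden.
#'
#' @param rain a [rainfall_series()].
#' @param threshold_mm onset threshold in millimetres (default 20).
#' @param year calendar year whose 1 September opens the search; defaults to
#'   the year of the first record.
#' @return the onset Date, or `NA` (undetermined) when no record qualifies.
#' @export
sowing_onset <- function(rain, threshold_mm = 20, year = NULL) {
  stopifnot(inherits(rain, "rainfall_series"))
  if (is.null(year)) year <- as.integer(format(rain$date[1], "%Y"))
  from <- as.Date(sprintf("%d-09-01", year))
  hit <- which(rain$date >= from & rain$accum_mm >= threshold_mm)
  if (length(hit) == 0) return(as.Date(NA))
  rain$date[hit[1]]
}
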