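Package: mcda
Title: Soybean Crop Mapping from 16-Day EVI Composite Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the MODIS crop detection algorithm (MCDA), a
    threshold-based classifier that maps soybean crop pixels from 16-day
    Enhanced Vegetation Index (EVI) composite time series. Builds the
    minimum-mean, maximum-mean and amplitude EVI images from calendar-windowed
    composite stacks, applies the calibrated Lmin/Umin/Amp thresholds together
    with a terrain mechanization mask (slope > 12% excluded), and supports
    first-forecast (prior-year peak image) and second-forecast modes with a
    rainfall water-deficit fallback. Includes threshold calibration from
    min/max EVI scatter, per-zone area estimation, multi-year expansion
    mapping, the stratified-sample confusion-matrix accuracy protocol
    (overall, user's and producer's accuracy, Kappa), regression diagnostics
    against official statistics, and a synthetic-scene generator so the whole
    pipeline is testable without satellite data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
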