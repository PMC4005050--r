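---
title: "Methods: threshold-based soybean detection from EVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based soybean detection from EVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcda)
```

## The model and its assumptions

The classifier exploits the phenological contrast between annual soybean and
everything else in a tropical mechanized-agriculture landscape. Soybean
fields are bare during the pre-sowing window (mid-August to early December)
and reach a dense green canopy six to ten weeks after sowing, so their EVI
trace shows a deep trough followed by a high peak within a fixed, regionally
known calendar. Savanna (cerrado) and forest keep a moderate-to-high EVI
year-round; water and cloud shadow sit near or below zero; December-sown
cotton is still early in its cycle during the soybean peak window.

Two window composites summarize a crop year:

* `min_mean_evi()` averages consecutive sowing-window composites (DOY
  225–337) two by two and takes the per-pixel minimum of the pair means.
  Pair averaging suppresses single-composite noise while the minimum tracks
  the trough; the operator is deliberately order-sensitive (pairs are
  consecutive in time).
* `max_mean_evi()` averages the four consecutive composites of the
  maximum-development window (DOY 353–033, wrapping the calendar year).
* their difference is the amplitude image.

Conditions A (`Lmin <= MinMean <= Umin`), B (`amplitude >= Amp`), C
(slope at most 12 %) and D (management mask) are conjunctive; the result is a
pure function of its inputs. The method assumes (i) a regionally stable crop
calendar expressible as fixed DOY windows, (ii) thresholds that are
physically driven and therefore transferable across crop years, and (iii)
fields large relative to the 250 m pixel (6.25 ha), so that mixed pixels are
confined to field borders.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `lmin` | 0.05 | EVI | floor of condition A; below it lie water and cloud shadow |
| `umin` | 0.39 | EVI | ceiling of condition A; above it lie perennial covers |
| `amp` | 0.36 | EVI | minimum green-up amplitude (condition B); set low enough to keep mixed border pixels |
| `slope_threshold_pct` | 12 | % slope | mechanization limit (condition C), exclusion strictly above |
| `strict_inequalities` | FALSE | — | closed vs open threshold comparisons |
| windows | 225–337 / 353–33 | DOY | sowing / maximum-development calendar |
| `pixel_area_ha` | 6.25 | ha | 250 m pixel area used in all area estimates |

The operational defaults are the published set for Mato Grosso. The source
lists them in the order "Umin, Lmin, Amp" = 0.05, 0.39, 0.36, which
contradicts the definitions (Lmin is the lower bound); the package ships the
only physically consistent assignment, Lmin = 0.05, Umin = 0.39, Amp = 0.36.
Threshold comparisons are closed by default so that the calibrated value
itself is admissible — Amp is defined as the smallest difference at which a
mixed soybean pixel is still designated soybean; `strict_inequalities = TRUE`
switches to open comparisons.

`sowing_onset()` reports the first dekad after 1 September with at least
20 mm of 10-day accumulated rainfall. It is advisory metadata only: no
quantitative rule for shifting the windows is defined, so the windows stay
fixed unless the user overrides them explicitly.

## Forecast modes and the water-deficit fallback

The second forecast uses both images of the current crop year. The first
forecast, released before the peak window has been observed, combines the
current sowing window with the peak image of the most recent prior normal
crop year; it therefore misses pixels newly converted to soybean (their
prior-year peak is low) — a documented limitation, exercised in the tests.
The same prior-year substitution is applied in the second forecast when no
usable peak composites exist or when `water_deficit()` detects 30 consecutive
days without a 10-day accumulation record above 10 mm. The deficit scan is
applied per supplied rainfall series and treated as scene-wide; attributing
stations to zones of influence is left to the caller. Fallback year
selection is deterministic: the most recent prior year with usable peak
composites that is not itself flagged as a deficit year.

## Calibration

The calibration thresholds are described in the source material only
verbally, via scatterplots of paired min/max EVI values over three 100 × 100
pixel test sites. The package operationalizes them deterministically, with
every constant exposed:

* `estimate_umin()` bins pairs into min-axis columns (width 0.01) and scans
  upward from Lmin for the first column in which more than 5 % of the mass
  lies within the diagonal band `|max − min| < 0.05` — the point where the
  min and max distributions converge (perennial vegetation). Degenerate
  samples without a convergent region return the 0.99 min-quantile with a
  warning; fewer than 1,000 pairs flag the estimate low-confidence.
* `estimate_lmin()` drops the water/shadow mode (values below 0) and returns
  the 1st percentile of the remaining minimum values.
* `estimate_amp()` takes, among pixels on the crop side of the scatter
  (min ≤ Umin) and outside the diagonal band, the 1st percentile of the
  amplitudes — the lower edge of the mixed-border cluster.

`freeze_parameters()` collapses per-year estimates to their medians (or to
user-pinned values such as the operational set) and validates the result;
per-year estimates are kept as an attribute for audit. No automatic
refitting against official statistics is provided: the published values also
reflect a manual adjustment loop against agency statistics whose objective
function is unstated, so automating it would be invention. Acceptance of the
calibration code is therefore by parameter recovery on synthetic scenes, not
by matching the published constants.

## Terrain

`slope_percent()` uses Horn's 3×3 weighted central differences — the GIS
standard — with border pixels handled by linear extrapolation (equivalent to
one-sided differences); a linear ramp reproduces its analytic slope to
1e-6 everywhere. `mechanization_mask()` excludes strictly above the
threshold (a pixel at exactly 12 % is kept). Because slope products are
typically 90 m and composites 250 m, `resample_mask_to_grid()` aggregates by
majority rule (a coarse pixel is mechanizable iff at least 50 % of its fine
cells are); the fine mask is thresholded before aggregation. Both the
majority fraction and this threshold-then-aggregate order are package
choices — the source is silent on grid reconciliation — and the fraction is
configurable.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure the classifier
assumes, not radiometry. Phenology is a periodic double-logistic curve per
class (green-up and senescence logistics multiplied), the standard
vegetation-index curve family; curve-shape constants are derived from each
class's sowing day, peak day and season length. The default mix is 30 %
single soybean, 15 % soybean→cotton, 10 % soybean→maize, 10 % single cotton
(December-sown, peaking after the soybean window), 20 % cerrado (minimum EVI
0.48), 10 % forest (0.55) and 5 % water, on rectangular fields sized around
the published mean field area (182.7 ha ≈ 29 pixels) — so fields are only a
few pixels across, as in reality. A 1-pixel boundary band between unlike
fields carries 50/50 mixed profiles, exercising the mixed-pixel role of Amp;
per-composite Gaussian noise (sd 0.02 EVI) is added and clipped to
[−0.2, 1]. The DEM is flat with one 25 %-slope stripe (5 % of rows by
default) and sits on the composite grid — the 90 m→250 m aggregation path is
tested separately with constructed fixtures. Zones are four quadrant
"municipalities". Rendering covers the sowing and peak windows of the target
and prior crop years, which is exactly what both forecast modes consume.

What the generator does **not** emulate: cloud-contamination structure
beyond nodata masks, sensor artifacts, inter-annual calendar drift, within
class phenological variability beyond i.i.d. noise, and irregular field
geometry. Passing the end-to-end tests therefore demonstrates correctness of
the algorithmic chain under the method's own assumptions, not real-data
skill.

The +30-day calendar shift of the soybean→cotton class reproduces the
documented double-cropping omission mechanism: producers delay soybean to
leave room for a long cotton cycle, the peak window catches the canopy
mid-rise, the observed amplitude falls to about 0.30 < Amp, and the fields
are omitted (producer's accuracy drops) while commission stays at zero
(user's accuracy holds).

## Numerical choices and degenerate inputs

* "Averaged two by two" is read as consecutive-pair means followed by the
  per-pixel minimum — deterministic and consistent with smoothing over a
  short window; it is the only mode offered.
* Pair means fall back to the surviving member when one member is masked
  (the input product is already gap-filled by maximum-value compositing);
  a pixel masked everywhere is nodata, and nodata pixels are `FALSE` in the
  classification with a separate nodata grid.
* More than four peak-window composites: the four starting at the window
  opening are used (the window is fixed), extras ignored with a warning.
  Fewer than four: error in strict mode (default), lenient mode averages
  what exists.
* Negative amplitudes are preserved, never clamped.
* Integer-scaled EVI (×1e-4) is auto-detected per file from integer values
  outside the float range, overridable.
* All randomness (scene, noise, sampling) flows through explicit seeds via
  an internal RNG-state-preserving helper; reruns are bit-identical, and
  writers emit byte-identical files.
* Ties: `stratified_sample()` samples without replacement within class and
  errors when a class is smaller than the request; `estimate_umin()` breaks
  ties by the first (lowest) convergent column.

## Problem sizes

The test suite runs 200 × 200 scenes (40,000 pixels, 24 composites) for the
end-to-end checks, 8 × 8 × 6 stacks for brute-force oracle comparisons,
10,000-point simulations for the double-RMSD coverage, and 10,000-pair
scatters for calibration — sizes at which every statistical check is stable
yet the whole suite completes in a few seconds.

## Known limitations

* Condition D is a pluggable mask defaulting to all-true; its published
  construction is defined only in antecedent material.
* The classifier cannot distinguish the second crop's species, nor estimate
  per-pixel sowing dates or yield.
* First-forecast maps systematically miss newly converted fields.
* Fields much smaller than the published mean (a few pixels) are dominated
  by their border band and will be under-detected — consistent with the
  reported field-size sensitivity.
* No reprojection or time-series smoothing is provided: inputs must share a
  grid, and raw composites are used by design.
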