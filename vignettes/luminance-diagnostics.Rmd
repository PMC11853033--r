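---
title: "Surface-luminance analysis of tissue samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-luminance analysis of tissue samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumipath)
```

## The measurement and the model

A photometric measuring head records the luminance L (cd/m²) reflected by
an ex vivo tissue sample lying on a uniformly illuminated, light-absorbing
bench. Neoplastic tissue reflects differently from healthy tissue, so a
calibrated map of per-pixel luminance carries diagnostic signal. The
analysis chain implemented here is:

1. **Load** a single-channel raster (16-bit grayscale TIFF or a CSV grid)
   and apply a linear calibration factor from raw counts to cd/m²
   (`load_luminance_map()`).
2. **Restrict** to a measurement field — the region of interest around the
   sample (`measurement_field()`).
3. **Segment** the field into half-open luminance bands and render them in
   pseudo-colour — green for lesion-free tissue, blue for suspected
   neoplastic tissue (`segment_by_bands()`, `render_pseudo_color()`).
4. **Detect lesion foci** as connected components of lesion-band pixels,
   with per-focus area, centroid and luminance statistics
   (`detect_foci()`).
5. **Summarise** the field: minimum, mean and maximum luminance
   (`summarize_field()`). The maximum, **Lmax**, is the single
   classification feature.
6. **Classify** each sample by an Lmax threshold and evaluate the rule
   against the histopathology reference: 2×2 tables, sensitivity,
   specificity, predictive values, likelihood ratios, overall agreement
   ("credibility"), a threshold sweep, ROC/AUC, χ² with Cramer's V, and a
   rank-based group comparison (`sweep_thresholds()`, `roc_curve()`,
   `chi_square_2x2()`, `rank_group_comparison()`).

The diagnostic layer is deliberately generic: it consumes any cohort table
`sample_id, group, l_max` and knows nothing about images.

## Classification direction: an unresolved polarity

The packaged fixture cohort (`fixture_lmax_table2()`) is reconstructed from
published cumulative threshold-assignment counts of 27 reference-positive
and 21 reference-negative samples. Those counts grow as the threshold
rises, which is only possible under the rule **positive ⇔ Lmax ≤ t**. Yet
the image-level characterisation in the same source says neoplastic foci
are *brighter* than healthy tissue (≈630–1130 vs ≈500–520 cd/m²), which
would imply the opposite polarity. The source's intent cannot be
recovered, so:

* the fixture and all frozen expectations use direction `"le"`, the only
  direction consistent with the published counts;
* both directions are first-class (`direction = "le"` / `"ge"`
  everywhere);
* a sweep whose best Youden J is negative raises a polarity warning. Note
  that positive-call counts themselves are always monotone across a sweep
  of a nested decision rule — in either direction — so non-monotonicity
  cannot be used as the diagnostic; a worse-than-chance J can.

The per-sample Lmax values inside the fixture are bin representatives
(midpoints; open bins use the bound ∓ 20 cd/m²). Only bin membership is
meaningful, and no test or report depends on the representative values
themselves. In that sense the fixture is a synthetic reconstruction, and is
documented as such.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `calibration_factor` | 0.025 | cd/m² per raw count | spans 0–1638 cd/m² over 16 bits, covering the ≈100–1300 cd/m² working range with 0.025 cd/m² resolution |
| `lesion_band_low` | 630 | cd/m² | healthy tissue peaks at 500–520 cd/m², the faintest lesion variant starts near 630; a configuration default, not a measured constant |
| `connectivity` | 8 | – | standard blob-analysis behaviour; 4 available |
| `min_area_px` | 5 | px | suppresses single-pixel specular-moisture artifacts reported for this bench |
| `thresholds` | 1070…1130 by 10 | cd/m² | the published sweep grid |
| `direction` | `"le"` | – | see above |
| `correction` | `"none"` | – | the uncorrected χ² formula reproduces the published statistic (27.86 on the (22,1,5,20) table); Yates' correction available but then the published value is *not* reproduced |

Threshold equality is positive in both directions; band intervals are
half-open `[low, high)` so bands always partition what they cover.

## The synthetic phantom generator

`generate_phantom()` emulates exactly the structure the analysis assumes:

* a dark background (default 100 cd/m², a black Lambertian cloth) with a
  smooth horizontal illumination gradient whose min/max ratio is the
  **evenness** parameter (default 0.98, the bench's stated uniformity);
* an elliptical tissue plateau at `tissue_level` (default 510 cd/m²);
* lesion foci as radially symmetric plateaus: flat at `lesion_peak` over
  `plateau_frac` of the radius, cosine falloff to `lesion_edge`
  (default 630 cd/m², the lesion-band floor) at the boundary, tissue level
  outside. Variant defaults follow the reported luminance ranges: advanced
  central lesion 900 cd/m², small single focus 645 cd/m², diffuse
  multifocal 700 cd/m²;
* optional specular artifacts (small disks at 1300 cd/m²) as confounders;
* additive Gaussian noise (default sd 2 cd/m²), truncated at zero.

Because the falloff never dips below the lesion-band floor inside a focus,
a noise-free phantom's rendered lesion pixels coincide exactly with its
ground-truth mask: `detect_foci()` must recover focus count, areas and
peak luminance *exactly*, and the tests require this. Under noise, focus
mean luminance is required to sit within 3·sd of the configured peak
(tested over 20 seeds with flat plateaus).

What the generator does **not** emulate: real tissue texture, staining,
moisture films, partial-volume edges, or the empirical Lmax distribution of
real cohorts (the published group moments are internally inconsistent and
cannot be targeted — the generator targets the published count *structure*
instead). A green test therefore establishes that the pipeline is
self-consistent and reproduces the published arithmetic, not that the
method works on real prostate tissue.

Cohort simulation (`generate_cohort()`) draws Lmax from location/scale
families; the defaults (positives N(1075, 45), negatives N(1150, 45),
truncated at 0) give overlapping groups with the "le" polarity and roughly
the published operating characteristics' difficulty — chosen once as a
realistic stand-in, not tuned to any statistic.

## Numerical and I/O choices

* **Rounding for display** is half-up to 2 decimals (`round_half_up()`),
  matching the published tables; full precision is kept internally.
  Undefined ratios (zero denominators) are explicit `NA`/"undefined"
  markers, never numbers. p-values below 0.001 display as "< 0.001".
* **ROC/AUC**: cut-offs at every distinct Lmax; ties grouped into single
  steps; trapezoidal area. This makes AUC identical to the Mann–Whitney
  pair statistic (concordant + ½·ties)/(n₊·n₋), property-tested over 100
  random cohorts against brute-force pair enumeration.
* **Threshold selection** maximises Youden's J over the user grid; ties
  break to the *largest* threshold (the published analysis adopted the
  larger of its two tied optima). All tied thresholds are reported.
* **Rank comparison**: normal-approximation rank-sum Z with tie correction
  and no continuity correction; effect size r = Z/√n. (With Z = 4.17 and
  n = 48 this formula gives 0.60, not the published 0.61; the formula
  behind the published value is unstated, and the discrepancy is
  documented rather than chased.)
* **Sample size for AUC** (`sample_size_auc()`): Hanley–McNeil variance,
  one-sided alpha, direct search over n₊ with n₋ = ⌈ratio·n₊⌉. The
  alternative AUC must be supplied explicitly — the value that would
  rationalise the published n = 48 at α = β = 0.01, ratio 0.7 is not
  recoverable from the source.
* **TIFF/PNG**: the package ships minimal codecs (uncompressed 16-bit
  grayscale baseline TIFF; 8-bit RGB PNG) because no TIFF/PNG package is
  available in the supported dependency set. Both are round-trip tested
  and cross-validated against independent third-party readers in the test
  suite. TIFF storage quantises to `round(value / calibration_factor)`;
  with the default factor that is 0.025 cd/m² resolution.
* **Connected components** are labelled via the pixel-adjacency graph
  (igraph); a brute-force flood-fill oracle in the tests checks exact
  agreement on random small maps under both connectivities.

## Known limitations

* No RAW-format ingestion, camera colorimetry, or vendor-software
  interop; the interchange format is the package's own (TIFF/CSV +
  explicit calibration factor).
* No automatic tissue/slide boundary detection: the measurement field is
  user-supplied (whole image by default — safe here because the phantom
  background is darker than tissue, so it never affects Lmax).
* Confidence intervals for sensitivity/specificity are not computed (the
  source names them without printing any; no method is specified).
* The polarity contradiction described above is surfaced, not resolved:
  with real data the user must verify which direction applies.
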