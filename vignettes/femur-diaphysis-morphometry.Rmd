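---
title: "Cortical bone morphometry and curvature of the femoral diaphysis from CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone morphometry and curvature of the femoral diaphysis from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femurmorph)
```

## The problem

The femoral diaphysis — the shaft between the lesser trochanter and the
adductor tubercle — carries most of the load of upright locomotion, and its
cortical (compact) bone is what determines the bone's strength. Two families
of quantities summarize a shaft cross-section and its course:

* **morphometry** of individual cross-sections: total cross-sectional area
  (CSA), area of cortical bone (ACB), their ratio the cortical index
  (CI = ACB/CSA), the periosteal border length (PBL), and the mean and
  maximum cortical bone thickness (CBT), where the thickness at a point of
  the outer (periosteal) surface is its minimum distance to the inner
  (endosteal) surface;
* **curvature** of the shaft as a whole: the anterior bow and the lateral
  deviation of the section reference points from the proximal–distal axis.

`femurmorph` implements this pipeline for CT volumes: a histogram-derived
Hounsfield-unit (HU) threshold separates cortical bone from air and marrow;
per-level binary masks yield the six morphometric parameters; an equal-area
section reference point (the *central mass distribution*, CMD) tracked along
ten evenly spaced levels quantifies curvature; and cohort-level statistics
(repeated-measures ANOVA with Scheffé post hoc, correlation PCA, chi-squared
tests, radiocarbon period grouping) compare populations. A synthetic phantom
generator with analytic ground truth makes every stage testable without any
scan data.

## Level plan and coordinate conventions

The user supplies two landmark slice indices: the lower end of the lesser
trochanter (proximal) and the adductor tubercle (distal). The span is divided
into nine equal segments; the ten bounding cross-sections are *levels* 1
(proximal) through 10 (distal), with positions rounded half-up to the nearest
slice. At the 0.5 mm slice thickness typical of clinical CT the rounding
error in any parameter is well below one percent, so no sub-slice
interpolation is performed. Morphometrics are reported for the eight interior
levels 2–9 by default; curvature uses levels 1–9 (nine sections), both
configurable.

Axes are (x, y, z) with z proximal→distal and y posterior→anterior. Left
femurs are mirrored about the sagittal plane on load so that +x is lateral
for every specimen; the mirror property (a mirrored volume with the flipped
side label yields identical morphometrics and patterns) is asserted in the
test suite. Indices are 1-based (R convention) with pixel centers at
`(index − 1) × spacing` mm.

## Segmentation

All pixels of the ten level sections are pooled into one HU frequency table
(default bin width 10 HU, bins centered on multiples of the bin width). Two
peaks are located: the air peak as the highest-count bin at or below
−500 HU and the bone peak as the highest-count bin at or above +200 HU, each
refined as the count-weighted mean over ±5 neighbouring bins. The gating at
−500/+200 HU makes the peak search robust to the broad mid-range mass of
marrow and soft tissue; the refinement removes the dependence on bin
placement. The cortical threshold is the **midpoint of the two peak means** —
a symmetric, parameter-free rule recorded in every mask's metadata so that
alternative rules remain comparable.

Per section, pixels at or above the threshold are foreground. The largest
8-connected foreground component is the cortical shell; isolated bone-valued
specks are discarded. Filling all interior holes gives the *section region*
(the periosteal interior); the largest 4-connected hole is the medullary
cavity, and smaller holes — trabecular voids, common in dry archaeological
bone — are merged into the cortex. The 8-connected foreground / 4-connected
background pairing is the standard duality that prevents both the region and
the cavity from leaking through diagonal gaps. Sections without a cavity are
flagged *solid*; their thickness is reported as undefined and excluded from
thickness statistics with a warning, rather than inventing an inner surface.

## Morphometry

Areas are pixel counts times the squared pixel pitch. PBL follows the
point-count convention — the number of boundary pixels times the pixel
pitch — because comparability with spreadsheet-based measurements of this
kind is the goal. This convention is exact for axis-aligned edges but
*underestimates* oblique and circular boundaries by up to ≈10% (a digital
circle of radius 75 px has 424 boundary pixels against a true circumference
of 471 px); a corrected chain-code perimeter (Kulpa's factor
π/8·(1+√2) ≈ 0.948 on the 8-connected boundary loop, accurate to ~1–2% on
smooth convex shapes) is logged alongside for diagnostics.

Thickness is the exact Euclidean minimum distance between pixel centers of
the periosteal and endosteal boundary point sets, with no sub-pixel surface
interpolation; tests allow ±1 pixel. The brute-force all-pairs minimum is
kept as an independent oracle in the test suite and must agree exactly with
the vectorized implementation.

Length standardization divides every parameter — areas included — by a
stated reference length (femoral total length or diaphyseal length). Because
the division is direct, standardized areas retain one length dimension
(mm²/mm); this is documented in the column units. Both reference lengths are
supported and the choice must be stated explicitly per analysis
(`reference_length_kind`), since either may be preferred depending on how
much of the epiphyses survive.

## Curvature

The CMD of a section is the intersection of the vertical and horizontal
lines that each split the section area into equal halves. The two splitting
lines are taken axis-aligned, consistent with reporting shifts per axis, and
the crossing of the cumulative column (row) sums is located with sub-pixel
linear interpolation **from both ends, averaged** — so a flat stretch of the
cumulative sum (disjoint lobes) splits at its midpoint, a deterministic
tie-break. The CMD is computed on the filled section region by default
(`region = "cortex"` is available). For any figure with two perpendicular
symmetry axes the CMD is the center to within 0.25 px; for asymmetric
sections it differs from the centroid, which is the point of the definition.

Deviations `dx` (lateral +) and `dy` (anterior +) at levels 1–9 are measured
from the 3-D straight baseline through the level-1 and level-9 CMDs,
parameterized by z; the endpoints are zero by construction. This per-axis
residual from the 3-D line reduces to the 2-D reading when levels are evenly
spaced. The anterior-curvature degree is summarized as the maximum
normalized `dy` across levels (the profile itself is also emitted), a scalar
chosen because the per-level profile alone does not order specimens.

The lateral pattern is classified from the signs of `dx` at the interior
levels 2–8 after zeroing shifts smaller than a deadband ε (default 0.3 mm,
one to two pixels at clinical CT resolution; exposed as a parameter since no
tolerance is inherent in the definition): all non-negative with at least one
positive → lateral primary curve; all non-positive with at least one
negative → medial primary; a single sign change → S-shaped, named by the
proximal side (`s_lateral_medial` = lateral at the top); all zero or more
than one sign change → indeterminate. Indeterminate profiles are counted
separately in contingency tables, never silently dropped.

## Statistics

* **Normality.** A chi-squared goodness-of-fit test against a normal with
  the sample mean and SD, equal-probability bins (default
  `max(4, ceiling(2 n^0.4))`), df = bins − 3.
* **Repeated-measures two-factor ANOVA.** Split-plot decomposition via
  `stats::aov` with an `Error(specimen)` stratum: cohort is the
  between-subjects factor, level the within-subjects factor, specimen the
  repeated unit nested in cohort. Sphericity is not corrected by default; a
  Greenhouse–Geisser option is provided (off by default, matching the
  uncorrected historical analysis). Specimens with missing levels are
  dropped listwise with a warning.
* **Scheffé post hoc.** Pairwise cohort contrasts on the between-subjects
  stratum: the contrast F is compared against
  `(k−1)·qf(1−α, k−1, df_between)`, never more liberal than an unadjusted
  pairwise F. Contrasts are computed on level-pooled cohort means by
  default; a per-level mode is provided (`scope = "per_level"`).
* **PCA.** On the correlation matrix (the six parameters carry
  heterogeneous units even after standardization), each component signed so
  its largest-magnitude loading is positive, for reproducibility.
* **Chi-squared independence.** Pearson statistic on the cohort × pattern
  table, all-zero rows/columns removed, a low-expected-count flag when any
  expected cell is below 5.
* **Period grouping.** Specimens are summarized by the midpoint of their
  highest-probability 68.3% calibrated interval and cut at 6,000 cal BP —
  the midpoint of the gap between the two period ranges (Initial/Early
  ca. 10,200–6,500, Late ca. 4,500–4,000 cal BP); any cut inside the gap
  gives the same grouping. Out-of-range midpoints are still assigned by the
  cut, with a warning.

## The phantom generator

`phantom_spec()` / `render_phantom()` build a bent hollow cortical tube in
air: per slice an (optionally tapering) elliptical annulus of bone HU around
a marrow-filled cavity, centered on a curved centerline, plus seeded
Gaussian HU noise. Defaults emulate the imaging conditions the pipeline
targets: 0.2 mm in-plane pitch, 0.5 mm slices, air −1000 HU, cortical bone
+1200 HU, noise SD 50 HU, outer radius 15 mm, wall 5 mm. Marrow defaults to
0 HU (water-like): the derived threshold for the default peaks is
(−1000 + 1200)/2 = 100 HU, and the cavity filler must sit clearly below the
threshold relative to the noise scale for the phantom to have a cavity at
all. An optional posterior angular thickness bump emulates the linea aspera;
note that under the minimum-distance definition a *narrow* bump's maximum
thickness is genuinely less than wall + extra (the nearest endosteal point
cuts the bump's corner) — the analytic truth accounts for this.

Curvature profiles are parameterized over the span between the level-1 and
level-9 slices, so both endpoints of the deviation baseline are zeros of the
profile and the per-level truth equals the profile values exactly: the
anterior bow is a half-sine of amplitude `bow_mm` peaking at level 5, the
primary lateral modes are half-sines of amplitude `lateral_mm` (signed by
side), and the S modes are full sines (zero also at level 5, signed by the
proximal side).

Ground truth — areas, CI, thickness, the CMD centerline, the deviation
profile and the pattern label — is derived from the analytic geometry, never
from the rendered voxels; for elliptical or ridged sections the thickness
truth is computed by dense sampling of the analytic boundary curves.

**What the phantoms do not emulate:** trabecular texture, partial-volume
blur at the cortical surfaces, beam hardening and scanner artifacts, cortical
porosity, and the irregular outline of real bone. Passing the recovery tests
therefore shows that the geometry pipeline is correct and noise-stable, not
that segmentation thresholds transfer to pathological or poorly preserved
specimens.

## Validation problem sizes and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses:
a 15 mm/10 mm annulus at 0.2 mm pitch for the area/thickness oracles
(agreement within 1% / 1 px); 20 random blob masks (150×150 px) for exact
agreement between the CMD and its brute-force oracle; 50 seeded noisy
replicates per lateral mode (amplitude 2 mm, noise SD 50 HU, ε = 0.3 mm)
for classification accuracy, plus noise-free replicates; 1000 simulated null
datasets and 500 shifted datasets (cohort sizes 10/10/5, 8 levels, shift of
2 between-specimen SDs applied to the first cohort — placed there because
the closed-form noncentrality gives ≥95% power for the size-10 cohort but
not for the size-5 cohort) for ANOVA calibration; and 120 synthetic
specimens with two orthogonal latent factors for the PCA structure check.
These sizes were chosen so each study estimates its quantity with comfortable
margin while the whole validation remains quick to run.

Other numerical choices, collected: histogram bins centered on multiples of
the bin width (so delta masses sit on exact peak values); round-half-up for
level positions (platform-independent, unlike banker's rounding); strict
`≥ threshold` for foreground; `<` for the phantom cavity test so boundary
pixels fall to bone; the equal-area crossing averaged from both ends;
boundary point sets defined as pixels with a background 4-neighbour,
extracted as ordered 8-connected loops.

## Known limitations

* The threshold rule (midpoint of the two peak means) is one defensible
  reading of histogram-based cortex definitions; the exact historical rule
  is not restated in the sources this package follows. The rule is recorded
  in every output for comparability.
* PBL's point-count convention underestimates oblique boundaries (≈10% for
  circles); use the logged geometric perimeter when absolute perimeters
  matter.
* Residual axial rotation of the specimen is not corrected; sections are
  taken perpendicular to the scanner z-axis, as in posterior-three-point
  positioning protocols.
* DICOM support is minimal by design: uncompressed explicit-VR
  little-endian, single-frame 16-bit slices (what this package writes and
  what typical clinical CT exports provide). Anything else should be
  converted to the raw-bundle format.
* Second moments of area, section moduli, bone mineral density calibration
  and biomechanical (finite-element or buckling) computations are out of
  scope.
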