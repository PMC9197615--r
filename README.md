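# femurmorph

Quantitative morphometry and curvature analysis of the femoral diaphysis
from CT volumes, for biological anthropologists and bone researchers
comparing cortical-bone geometry across individuals or populations
(including archaeological material).

## What it computes

Given a CT volume of a single femur and two landmark slices (lower end of
the lesser trochanter, adductor tubercle), the span is divided into nine
equal segments bounded by ten *levels*. A cortical threshold is derived from
the pooled Hounsfield-unit histogram of the ten level sections as the
midpoint of the air peak (≈ −1000 HU) and the bone peak. Each thresholded
section yields six morphometric parameters:

| parameter | definition |
|---|---|
| CSA | cross-sectional area enclosed by the periosteal perimeter, mm² |
| ACB | area of cortical bone (between periosteal and endosteal perimeters), mm² |
| CI  | cortical index = ACB / CSA |
| PBL | periosteal border length: boundary-point count × pixel pitch, mm |
| mean CBT | mean over periosteal points p of min<sub>q ∈ endosteal</sub> ‖p − q‖, mm |
| max CBT  | maximum of the same minimum-distance thickness map, mm |

all optionally standardized by femoral total or diaphyseal length.

Shaft curvature uses the *central mass distribution* (CMD) of each section —
the intersection of the vertical and horizontal lines each splitting the
section area into equal halves. With deviations d**x** (lateral +) and
d**y** (anterior +) of the level-1…9 CMDs from the straight baseline through
the level-1 and level-9 CMDs, the anterior-curvature degree is
max<sub>level</sub> dy / reference length, and the signs of dx at levels 2–8
classify the lateral pattern: lateral or medial *primary* curve (single
sign), or *S-shaped* with a single sign change, named by the proximal side.
Cohort statistics include a split-plot repeated-measures ANOVA with Scheffé
post hoc, correlation PCA of specimen means, a chi-squared independence test
on the pattern contingency table, a chi-squared goodness-of-fit test for
normality, and period grouping from calibrated radiocarbon ages.

A synthetic phantom generator (`phantom_spec()` / `render_phantom()` /
`render_cohort()`) renders bent hollow cortical tubes with analytic ground
truth — controllable wall thickness, anterior bow, four lateral-curvature
modes, a linea-aspera-like posterior ridge, and seeded HU noise — so the
whole pipeline is testable without scan data.

## Worked example

Render a noisy phantom with a 4 mm anterior bow, a 2 mm S-shaped lateral
curve (medial at the top) and a 5 mm cortical wall, then run the pipeline:

```r
library(femurmorph)

spec <- phantom_spec(bow_mm = 4, lateral_mode = "s_medial_lateral",
                     lateral_mm = 2, thickness = 5, noise_sd = 50, seed = 42)
vol  <- render_phantom(spec)$volume

plan     <- plan_levels(vol, z_upper = 1, z_lower = 91)
sections <- extract_sections(vol, plan)
thr      <- derive_threshold(pool_histogram(sections))   # 100 HU
measure_specimen(sections, thr)
#>  level    csa    acb    ci  pbl mean_cbt max_cbt
#>      2 706.96 393.12 0.556 84.4    4.953   5.091
#>      3 706.32 392.84 0.556 84.4    4.960   5.099
#>      4 707.00 393.00 0.556 84.4    4.953   5.060
#>      5 706.52 393.76 0.557 84.8    4.972   5.200
#>      ...
```

The true values are CSA = π·15² = 706.86 mm², ACB = π(15²−10²) = 392.70 mm²,
CI = 0.5556 and a 5 mm wall: every level is recovered within 1% (areas) and
one pixel (thickness). PBL (84.4–84.8 mm) illustrates the point-count
convention's known ≈10% underestimate of the true 94.25 mm circumference on
circular outlines; the logged geometric perimeter is within 2%.

```r
curvature_profile(vol, 1, 91, reference_length = 430)
#> <deviation_profile> pattern s_medial_lateral, anterior degree 0.009299 (ref 430 mm, eps 0.30 mm)
#>   level  z     x     y     dx    dy   dx_norm  dy_norm
#> 1     1  0 22.00 22.00  0.000 0.000  0.000000 0.000000
#> 2     2  5 20.59 23.52 -1.415 1.524 -0.003290 0.003544
#> 3     3 10 20.00 24.83 -2.000 2.833 -0.004651 0.006588
#> 4     4 15 20.59 25.70 -1.414 3.695 -0.003288 0.008594
#> 5     5 20 22.00 26.00  0.000 3.999  0.000000 0.009299
#> 6     6 25 23.41 25.70  1.414 3.695  0.003288 0.008594
#> ...
```

The deviation profile recovers the planted geometry: dx is negative (medial)
at proximal levels and positive (lateral) distally with the planted 2 mm
amplitude at levels 3 and 7, dy peaks at 4.0 mm at mid-shaft, and the
specimen is classified `s_medial_lateral`.

For a full cohort run, `femurmorph simulate --out phantoms --seed 1` writes
raw bundles plus a ready `config.yaml`, and `femurmorph report --config
phantoms/config.yaml` produces the measurement CSVs, CMD profiles, the
cohort × pattern contingency table with its chi-squared report, ANOVA/Scheffé
tables and PCA loadings/scores.

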