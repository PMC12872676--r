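# widefieldGCIPL

Normative analysis of ganglion cell–inner plexiform layer (GCIPL) thickness
from **widefield OCT** (55° × 45°, 109 B-scans 120 µm apart). The package is
for vision scientists and OCT methodologists who have per-eye boundary
segmentations (RNFL–GCL and IPL–INL surfaces) and want demographically
comparable thickness maps plus a characterisation of how the GCIPL ages
across the scanned retina — or who want to prototype such analyses on fully
synthetic eyes.

## What it computes

**Geometry.** Axial thickness between the two boundaries is corrected into a
comparable 160 × 160 grid of 100 × 100 µm fovea-centred squares:

- vertical scan curvature reconstructed from an ellipse fitted to the foveal
  B-scan, with the vertical long axis
  `axis_vert = (−0.004072·rx + 0.9921) · axis_horiz`;
- axial length from biometry, or from refraction when unmeasured:
  `AL = −0.412·rx + 23.757` (mm);
- de-warping so boundaries stay equidistant from the ocular nodal point
  (reduced schematic eye, configurable);
- retinal tilt θ (radians) from surface gradients, and the
  tilt-perpendicular thickness
  `GCIPL_corr = GCIPL_uncorr − 14.03·θ² + 1.611·θ − 0.07437` (µm);
- transverse magnification: `lateral resolution × AL / 24.385`;
- row-wise interpolation of vessel-shadow exclusions (macular, peridisc and
  edge zones protected), mirroring of left eyes, rotation to the individual
  fovea–disc axis, then grid averaging.

**Statistics.** Multiple regression of global thickness on age, axial length
and sex with a 10 % coefficient-change backward-elimination rule; the
repeatability coefficient `C_R = 1.96·√(Σ|m−c|/n)`; decade age-bracket
pooling; spatial clustering of bracket profiles by within-groups-linkage
hierarchical and two-step algorithms, with the cluster count chosen as the
largest k with mean silhouette ≥ 0.5 and adjacent-pair
`d′ = |x̄₁−x̄₂|/√(0.5(σ₁²+σ₂²)) ≥ 1`; sliding decade-window
linear-vs-quadratic extra-sum-of-squares F comparison; and per-cluster
ageing regressions via linear mixed models (random eye intercept) with
estimated marginal means, likelihood-ratio/F shared-slope tests and
Tukey-adjusted slope contrasts.

**Synthetic eyes.** `generateCohort()` / `truthMap()` / `distortToRaw()`
emulate the study conditions — 470 eyes in decade brackets
(70/73/70/80/102/75), AL ~ N(23.97, 1.12) mm coupled to refraction, fovea–disc
tilt ~ N(7.14°, 3.87°), a nine-cluster concentric thickness model with
per-cluster ageing slopes (−0.04/−0.12/−0.19 µm/yr), and all acquisition
distortions (curvature flattening, nodal warpage, magnification, rotation,
vessel shadows) — so the full cascade round-trips against known truth.

## Worked example

```r
library(widefieldGCIPL)

cfg   <- generatorConfig(nEyes = 12L, bracketCounts = rep(2L, 6), seed = 3L,
                         missingAlFraction = 0)
eye   <- generateCohort(cfg)[1, ]
truth <- truthMap(eye, eyeNoiseSd = 0, squareNoiseSd = 0)
vol   <- distortToRaw(truth, eye, cfg, seed = 9L)
res   <- processVolume(vol, matchingOptions(cfg))

res$grid
#> ThicknessGrid: 160 x 160 squares of 100 um
#>   defined: 19121 (74.7%), mean 47.7 um
#>   alignment tilt removed: 13.71 deg; eye: eye0001

g <- gridValues(res$grid); tv <- gridValues(truth); ok <- is.finite(g)
mean(abs(g[ok] - tv[ok]))
#> [1] 0.2448222
```

The recovered grid differs from the generating truth by 0.24 µm on average —
well inside the 3.87 µm axial resolution of the instrument — after the
cascade has undone every distortion the generator applied (the residual sits
at cluster boundaries blurred by resampling). A study-scale cluster run:

```r
stack <- syntheticBracketStack(seed = 17L)        # 470-eye bracket stack
sol   <- selectK(stack, algorithm = "hierarchical")
sol
#> ClusterSolution (hierarchical): k = 9
#>   mean silhouette: 0.869
#>   cluster means (um): 30.9, 36.5, 46.1, 56.5, 65.8, 74.3, 82.5, 90.2, 97.1
#>   adjacent d': 6.22, 5.83, 4.88, 3.32, 2.60, 2.54, 2.38, 2.15
```

Nine clusters pass both gates, and the labels reproduce the generating
concentric template exactly. `runPipeline(pipelineConfig(list(outDir = "run",
seed = 7)))` chains simulate → process → cluster → regress → report on disk
with a checksum manifest; `reportRun("run")` regenerates the report.

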