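---
title: "Methods: widefield GCIPL thickness mapping and its ageing analysis"
author: "widefieldGCIPL"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: widefield GCIPL thickness mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model behind the geometry cascade, the statistical procedures, what the
synthetic-eye generator does and does not emulate, and the numerical and
design choices a maintainer would want recorded. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The measurement problem

Widefield OCT volumes (55° × 45°, 109 B-scans spaced 120 µm) cover far more
retina than macular protocols, but the raw boundary exports are not
comparable across eyes. Four geometric effects intervene:

1. **Lost vertical curvature.** B-scans are acquired one at a time along the
   horizontal meridian; each is placed in the frame independently, so the
   posterior globe's curvature along the vertical meridian is absent from
   the export.
2. **Acquisition warpage.** Depth is recorded along beams pivoting about the
   eye's nodal point, which flattens curved anatomy ("OCT flattening").
3. **Retinal tilt.** The axial distance between two boundaries overestimates
   the anatomical (boundary-perpendicular) thickness wherever the retina is
   inclined to the beam — increasingly so with eccentricity, which makes the
   correction essential at widefield eccentricities.
4. **Transverse magnification.** Lateral scale depends on axial length, so
   identical pixel offsets land on different retinal locations in long and
   short eyes.

`processVolume()` undoes them in order. Vertical curvature is reconstructed
by translating each B-scan onto a circular arc whose radius comes from an
ellipse fitted to the foveal B-scan, scaled by
`axis_vert = (−0.004072·rx + 0.9921)·axis_horiz`. De-warping restores each
boundary point to constant distance from the nodal point. Tilt is computed
from finite-difference surface gradients in physical units, and thickness is
corrected by the quadratic
`GCIPL_corr = GCIPL_uncorr − 14.03·tilt² + 1.611·tilt − 0.07437` (µm, tilt in
radians). Lateral resolution is rescaled by `AL/24.385`. Finally, exclusions
are interpolated row-wise, left eyes are mirrored to right-eye orientation,
the frame is rotated so the individual fovea–disc axis is horizontal, and
values are averaged over a fovea-centred 160 × 160 grid of 100 × 100 µm
squares. The grid deliberately exceeds the scan footprint, so edge squares
are missing by construction.

Assumptions worth making explicit: tilt is treated as a **magnitude**
(the sign convention of the correction's linear term is not derivable from
the published form; the quadratic's maximum is −0.0281 µm, so the
correction is negative for any real tilt either way); the tilt reference
plane is the instrument horizontal through the foveal centre; and the
nodal point follows a reduced schematic eye, 7.1 mm behind the cornea at
the 24.385 mm reference length and scaled by `AL/24.385`
(`processingOptions(nodalDistMm=)` overrides it).

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `axialScaleUmPerPx` | 3.87 | µm/px | instrument axial resolution; also the error yardstick for the round trip |
| `nodalBehindCorneaMm` | 7.1 | mm | reduced-eye nodal depth at reference AL |
| `macularZoneUm` | 2300 | µm | ≈ 8° macular protected zone: interpolation is unreliable where thickness varies fastest |
| `discZoneFactor` × `discRadiusUm` | 1.5 × 900 | — , µm | peridisc protected zone |
| `minFrac` | 0.5 | — | a grid square must have ≥ 50 % of its samples defined; balances coverage against noise |
| `upsample` | 4 | — | vertical resampling between 120 µm B-scan rows onto ~30 µm spacing, standing in for the bicubic resize of boundary maps to SLO dimensions |
| `minSilhouette`, `minDPrime` | 0.5, 1 | — | cluster-count gates |
| bracket edges | 20, 30, …, 70+ | years | decade pooling used throughout |

All of these live in `processingOptions()` / `pipelineConfig()`, so
sensitivity analyses need no code change.

## Statistical procedures

*Global demographics.* OLS of grid-mean thickness on age (yr), axial length
(mm) and sex (0 male, 1 female). `backwardElimination()` removes the least
significant main effect and refits; if any remaining coefficient moves by
more than 10 %, the removed effect is restored and the procedure stops. Note
the procedure intentionally has **no significance gate on the removed term**
— it mirrors the described protocol, where even a significant term is
trialled for removal and the 10 % rule decides. With mutually orthogonal
regressors it therefore reduces the model further than a p-value-gated
stepwise would.

*Repeatability.* `repeatabilityCoefficient()` implements
`C_R = 1.96·√(Σ|m−c|/n)` exactly as published. This differs from the
conventional Bland–Altman repeatability coefficient (1.96 × SD of
differences) — the mean absolute difference sits under the root, which gives
`C_R` square-root units and the homogeneity property
`C_R(c·d) = √c·C_R(d)` (property-tested). Whether that form is intentional
cannot be resolved from the available description of the protocol; `convention = "classic"`
provides the conventional statistic.

*Clustering.* Features are the six decade-bracket mean adjusted thicknesses
per square, unstandardised (µm) — bracket means are already on a common
scale and standardising would distort the µm separability the d′ gate is
meant to measure. Hierarchical clustering uses squared Euclidean distance
with **within-groups linkage** (each merge minimises the merged cluster's
mean within-cluster squared pairwise distance), implemented directly because
`stats::hclust` lacks this linkage; ties merge at the lowest column-major
pair index, which makes the dendrogram deterministic. Two-step clustering
pre-clusters into 64 sub-clusters with k-means over lexicographically sorted
profiles (initialised from evenly spaced sorted unique rows, hence
deterministic and input-order invariant) and agglomerates sub-clusters with
a log-likelihood distance `ζ(a)+ζ(b)−ζ(ab)`,
`ζ(v) = −N_v Σ_f ½·log(σ̂_f² + s²_vf)`, the continuous-variable form of the
classic two-step criterion. `selectK()` returns the largest k ≤ kMax whose
mean silhouette is ≥ 0.5 and whose **adjacent-pair** d′ (after ordering
clusters by mean thickness) is ≥ 1; with nine ordered concentric clusters,
all-pairs separability at the extremes follows from adjacent separability,
and `pairs = "all"` enables the stricter rule. If no k passes, a k = 1
sentinel is returned with full diagnostics. Silhouette uses the standard
(b−a)/max(a,b) with the 0/0 → 0 convention for coincident points and is
cross-checked against `cluster::silhouette` in the tests.

*Ageing regressions.* Per-eye cluster means are modelled with
`lmer(value ~ age*cluster + (1|eye))` — a random intercept per eye only, as
the within-eye correlation is induced by each eye contributing one value per
cluster. Estimated marginal means are evaluated at decade-bracket midpoints
(25…75) with equal weights; the reference grid is otherwise unstated, and
midpoints only shift intercepts. Log-scale analyses use log₁₀: the reported
log intercepts (≈1.5–2.0 against thicknesses of 33–107 µm) are consistent
only with base 10. Shared-slope testing combines the mixed-model likelihood
ratio (ML refits with and without the interaction) and the extra-SS F on the
pooled OLS analogue; post-hoc slope contrasts use `emmeans::emtrends` with
Tukey adjustment; `slopeGroups()` greedily merges thickness-ordered clusters
while all within-group contrasts stay non-significant. Because the grouping
inherits the 5 % family-wise error, exact group recovery is asserted over a
majority of replicates, not a single draw.

*Pooled bracket fits.* When a per-cluster slope is fitted to bracket-pooled
means, the bracket means are weighted by bracket size. The brackets are
unequal (70–102 eyes), so equal-weight OLS on the six means is mildly
miscalibrated (its nominal 95 % CI covers ≈ 90 % of the time); weighting by
`n_b` is the exact generalised-least-squares form and restores nominal
coverage. Point estimates are essentially unchanged.

## The synthetic-eye generator

`generateCohort()` reproduces the cohort structure: decade brackets of
70/73/70/80/102/75 eyes, ages uniform within brackets, axial length
N(23.97, 1.12) mm truncated to [20, 28], refraction generated by inverting
the biometry regression plus N(0, 1) D scatter (clipped to the ±6 D
inclusion range, giving the intended strong negative coupling), sex
Bernoulli(262/470), laterality Bernoulli(247/470), fovea–disc tilt
N(7.14, 3.87)°, IOP carried but unused. A configurable fraction of eyes has
axial length withheld to exercise the refraction fallback.

`truthMap()` builds ground truth from a nine-cluster concentric template
(nested ellipses, vertical ratio 0.8, centres displaced nasally for rings
beyond 3.6 mm — the reported pattern constrains topology, not coordinates,
so ring radii are free parameters chosen to make cluster areas grow with
eccentricity) with per-cluster lines plus demographic effects. Noise is an
eye-level offset (5 µm) plus independent per-square noise (3 µm): a ~5.5 µm
per-eye-cluster residual cannot arise from independent per-square noise
alone, because averaging across a cluster's squares would shrink it. Real
spatial autocorrelation between neighbouring squares is **not** simulated
(both SDs are configurable); passing tests therefore demonstrate correctness
of the estimators under the stated noise model, not robustness to spatially
correlated segmentation error.

`distortToRaw()` emits raw boundary volumes by applying, per toggle, the
inverse of each correction: thickness inflation by the inverse tilt
polynomial under a spherical-cap surface (radius AL/2), nodal-point warpage
followed by removal of vertical curvature (the flattening offsets are
computed with the cascade's own ellipse-fit code on the emitted foveal
B-scan, so reconstruction is the exact inverse by construction), lateral
scaling, rotation by the eye's fovea–disc tilt with left eyes mirrored, and
Poisson vessel-shadow runs plus a peridisc exclusion. It does not simulate
speckle, A-scan intensities, or segmentation failure modes. The processing
options applied downstream must match the distortions applied — that is what
`matchingOptions()` encodes, mirroring real pipelines where the instrument
always warps and the software always de-warps.

## Numerical choices and degenerate inputs

- **Ellipse fitting** first tries the algebraic axis-aligned conic
  (`x² + C·z² + D·x + E·z + F = 0`, linear least squares; exact on true
  ellipses). Raw warped exports are locally near-parabolic and often make
  the unconstrained conic hyperbolic; the fallback fits the fovea-centred
  arc `z = c + b(1 − √(1 − (x/a)²))` by Nelder–Mead (reltol 1e-14,
  initialised from the apex curvature of a quadratic pre-fit). Both routes
  are invariant to constant z offsets. Flat or inverted profiles, < 5
  defined points, or RMS residual > 200 µm raise the atypical-macular-profile
  exclusion rather than defaulting.
- **De-warp** uses depths relative to the foveal IPL–INL position; the
  planar limit (`nodalDistMm = Inf`) is the identity, and a nodal point
  inside the imaged retina is an error.
- **Grid averaging** floors defined squares at 0 µm; squares with no samples
  or with a defined fraction below `minFrac` are missing.
- **Tie-breaks**: agglomerative merges take the lowest column-major index;
  nearest-centroid broadcast uses the first minimum.
- **Determinism**: all randomness flows from explicit seeds; pipeline stages
  derive per-stage, per-eye seeds from the single config seed, and two runs
  with the same config produce byte-identical artifacts (checksummed in the
  run manifest).

## Problem sizes

Cluster analysis operates on bracket profiles per grid square; the
within-groups linkage is O(n²) in memory and worse in time, so the package
clusters a 4×-decimated template (40 × 40 → ~1600 squares) by default and
broadcasts labels to the full 160 × 160 grid by nearest-centroid profile
assignment (`cluster$stride` in `pipelineConfig()`). The test suite uses a
20 × 20 stack for unit-level recovery and the 40 × 40 stack for the
selection study; geometry round trips run 12 synthetic eyes at full scan
size (109 × 512). Recovery studies refit 200 replicates at the study's
n = 470.

## Interface note

The pipeline is exposed as R functions (`runPipeline()`, `reportRun()`,
stage functions and the I/O layer) rather than a shell executable; R users
script these directly, and `scripts/acceptance.R` shows the headless usage
pattern.

## Known limitations

- The tilt sign convention and the exact nodal-point formula of the original
  processing chain are not derivable from the available description of the protocol; both are
  configurable, and the round-trip tests validate internal consistency, not
  agreement with the vendor chain.
- The protocol's reported sex coefficient appears as −0.646 in the coefficient table
  and −0.464 in the summary text; the table value is used throughout.
- The reported 42.57 % axial-length coefficient change is not reproducible
  from the reported coefficients by the stated formula
  (100·|−0.436 − (−0.371)|/0.436 ≈ 14.9 %); `coefficientChangePct()` reports
  the formula-defined value.
- Interpolation operates on A-scan columns of the corrected thickness map;
  whether the original chain interpolated before or after resampling to SLO
  pixels is unknown. The protected zones make the difference immaterial for
  the grid statistics.
- Ethnicity effects, visual-field mapping and segmentation itself (the
  package consumes boundary surfaces) are out of scope.
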