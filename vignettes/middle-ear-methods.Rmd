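---
title: "Methods: sinus volumetrics, allometry and middle-ear acoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sinus volumetrics, allometry and middle-ear acoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratymp)
```

`paratymp` implements a quantitative pipeline for ontogenetic studies of the
crocodylian paratympanic (middle-ear) sinus system: compartment volumetrics
on segmented CT label volumes, geometric-mean skull-size morphometrics,
reduced-major-axis allometry with isometry tests, and a Helmholtz-resonator
model of the middle-ear air space. This vignette is the package's account of
those methods: the models and their assumptions, the parameters that matter,
the numerical choices, and what the synthetic test data do and do not
establish.

## Label-volume volumetrics

A `label_volume` is a 3D grid of integer labels with per-axis voxel spacing
in mm; label 0 is background and each positive label is one sinus
compartment. The centre of voxel `[1,1,1]` sits at the physical origin and
all derived coordinates (meshes, apertures) are in mm.

**Volume** is defined as voxel count times the physical voxel volume. This
is the canonical definition throughout the package: it is exact for the
labelled region, conserved under any relabelling, and independent of
meshing. A mesh-enclosed volume (divergence theorem over a closed
triangulated boundary) is also provided for cross-checks; on smooth shapes
the two agree to well under 1% at the resolutions used here.

**Surface area** has two estimators. `voxel_faces` sums exposed voxel faces;
it is exact for axis-aligned solids (a 10 mm cube measures exactly
600 mm²) but systematically overestimates curved surfaces (by a factor
approaching 1.5 for a sphere), because staircases do not shorten as
resolution grows. `isosurface` — the default — triangulates the compartment
boundary and sums triangle areas. The extractor pads the binary mask with a
background shell, Gaussian-smooths it (`smoothing_sigma`, default 1 voxel),
and polygonises the 0.5 level with marching tetrahedra. Smoothing matters:
the raw binary level set inherits the staircase and its area error, while
the smoothed level set tracks the underlying smooth anatomy. On a rasterized
ball of radius 32 voxels the smoothed isosurface area is within 0.2% of
4πr² (the tests require 3%), and the error falls monotonically with
resolution. For axis-aligned solids, set `smoothing_sigma = 0`: the raw
level set is then exact and smoothing would only round the corners.

The marching-tetrahedra scheme splits every grid cell into six tetrahedra
around the main diagonal; the induced face diagonals are
translation-invariant, so neighbouring cells always agree and the surface is
watertight whenever the padded mask keeps the compartment off the grid
boundary. Samples exactly at the 0.5 level are nudged by 1e-7 so
interpolation parameters stay strictly inside (0,1) and no zero-area
triangles arise. Triangles are oriented outward at construction (checked
against the inside corners of each tetrahedron), so the divergence-theorem
volume needs no global orientation pass.

**Apertures** are planar polygon loops in mm. The area is computed by fan
triangulation about the centroid, which is exact for convex and mildly
non-convex loops. Planarity is enforced at 2% of the loop diameter
(maximum point-to-plane distance, plane fitted by SVD); beyond that the
loop is rejected as degenerate rather than silently projected.

## Constriction splitting

Confluent sinus diverticula meet at well-defined necks, like conjoined soap
bubbles. `split_at_constrictions()` operationalises that qualitative
criterion:

1. Euclidean distance transform of the binary compartment, computed in
   physical mm (Felzenszwalb–Huttenlocher, per-axis spacing respected), so
   anisotropic scans are handled correctly.
2. Gaussian smoothing of the transform (`smoothing_sigma`, default 1 voxel)
   to suppress voxel-scale plateau noise in the peaks.
3. Regional maxima (26-connected plateaus) seed a marker-based watershed
   (priority flood, 6-connected, deterministic FIFO tie-break), which
   assigns every compartment voxel to a candidate lobe.
4. A neck audit: for each adjacent lobe pair, the neck radius is the maximum
   distance-transform value on the shared interface, and the split is
   accepted only when `neck < neck_ratio × min(lobe radii)`, where a lobe's
   radius is its maximum inscribed-sphere radius. Failing boundaries are
   merged away, worst first, until all surviving boundaries are genuine
   constrictions.

`neck_ratio` (default 0.8) is the one tunable judgement call: 0.8 accepts
the neck between two equal spheres whose centres are 1.8 radii apart (neck
0.44 R) with a wide margin, while refusing to cut blobs whose "neck" is
nearly as wide as the lobes themselves. Voxel membership is conserved
exactly — the watershed covers the mask and merging only relabels — and the
operation is idempotent: accepted lobes contain a single distance peak each,
so re-running splits nothing further. Accepted lobes get fresh labels above
the current maximum, with legend entries suffixed `.lobe1`, `.lobe2`, so no
existing label is ever silently reused.

On the two-sphere phantom (radii 20 voxels, centres 36 voxels apart) the
recovered interface lies within one voxel of the analytic radical plane and
each lobe volume is within 5% of the closed-form sphere-minus-half-lens
value.

## Geometric-mean skull size

`geometric_mean_size()` computes `(prod m_i)^(1/k)` in log space over the
27 linear skull measurements. Two printed measurements share one anatomical
name (infratemporal fossa width); the schema keeps 27 distinct keyed slots
(`_a`/`_b`) to preserve the printed count. Whether every specimen has all
27 measurements is left configurable (`require_complete`): skeletal
specimens can lack soft-tissue-dependent measures, so by default the mean is
taken over the k values present and k is recorded on the result. The
composite is scale-equivariant, bounded by the extreme measurements, and
invariant to measurement order — all property-tested.

## Reduced-major-axis allometry

All variables are log-transformed before regression. The base is log10
(slopes are base-invariant; intercepts are documented as base-10). SMA is
the right line for allometry because both axes carry biological variation:
the slope is `sign(r)·s_y/s_x`, which is symmetric under axis swap
(slopes multiply to 1, tested to 1e-10) and equals the geometric mean of the
two OLS slopes (the independent oracle in the tests).

The slope CI uses `B = F(1-α; 1, n-2)(1-r²)/(n-2)` with bounds
`slope·(√(B+1) ± √B)`; the isometry test correlates the residual axis
`y - b₀x` with the fitted axis `y + b₀x` and refers
`t = r_rf √((n-2)/(1-r_rf²))` to Student t with n-2 df, two-sided, at
α = 0.05. Both follow the standard SMA literature, stated here in full so
no external package is required. Monte-Carlo checks in the test suite
confirm the nominal behaviour at the study's sample size (n = 13): 95% CI
coverage within 95 ± 3% over 500 simulations and type-I error within
0.05 ± 0.015 over 2000 replicates.

Degenerate inputs are contracts, not crashes: exactly collinear data yield a
zero-width CI flagged `exact`; data lying exactly on the null slope return
p = 1 (detected with a relative tolerance of 1e-12 on the residual SD, since
floating-point residuals are never exactly constant); an exact line away
from the null reports p = 0 with an `infinite_statistic` flag; zero variance
on either axis is an error naming the axis. The three standard regressions
(middle-ear volume on GMS, on braincase volume, on tympanum area; nulls 3,
1, 1.5) are run without multiple-testing correction, matching standard
practice for a small fixed family of planned comparisons.

## Helmholtz acoustics

The middle-ear cavity is modelled as a Helmholtz resonator,
`f = (c/2π)√(A/(L·V))`. The end corrections are fixed at γ = 1.4 (unflanged,
`L = l + 1.4r`) and γ = 1.7 (flanged, `L = 1.7r`, actual neck length zero);
the acoustics literature's other end-correction conventions (0.6–0.85·r)
are deliberately not used, because these two constants define the model this
package implements. Overriding them is possible but announced. The aperture
radius for non-circular openings is the equivalent-circle radius √(A/π) —
only the area is measurable on a specimen.

Choices the measurements do not fix, left configurable and logged: the
speed of sound (default 343 m/s, dry air at 20 °C; frequencies scale
linearly in c) and whether both candidate apertures share one cavity volume
(default yes: the sinus system is contiguous, so the whole middle-ear
volume loads either aperture). Internally everything is SI; mm inputs are
converted only in the `resonator_geometry()` constructor, and the mm path
agrees with direct SI evaluation to 1e-12 (tested). The frequency is
evaluated in log space, so extreme magnitudes cannot overflow.

Two exact scaling laws anchor the tests: isometric scaling (A×k², l×k,
V×k³) gives f → f/k, and log f against log size has SMA slope exactly −1,
which ties the acoustics module to the allometry module. Consequently a
geometrically growing middle ear cannot hold its tuning: a 19-fold size
range implies a 19-fold frequency drift. A narrow observed band across
ontogeny therefore implies compensatory growth — the motivation for the
generator's frequency-locked mode below.

## The synthetic-data generator

`generate_growth_series()` emulates the structure of the study's
ontogenetic series: n = 13 specimens by default, dorsal skull length (DSL)
drawn log-uniformly over 29.26–551.6 mm. Log-uniform is a deliberate choice:
real salvage series are size-biased toward juveniles, and log-uniform covers
the 19-fold range evenly in the log metric in which all analyses operate.
The 27 measurements are fixed fractions of DSL (arbitrary positive
constants, fixed in the package) with independent lognormal noise
(default SD 0.02 in log10, matching the log-transform-then-regress analysis
model); middle-ear volume, tympanum area and braincase volume are power laws
of the *realized* GMS — so noiseless runs are exactly collinear in log
space — with exponents `beta_me` (default 1.9735), `beta_tsa` (default
`beta_me/1.4448`) and `beta_bc` (default `beta_me/0.8273`). The defaults
make the three standard regressions recover slopes 1.9735, 1.4448 and
0.8273; `isometric_growth_config()` (betas 3, 2, 3) makes them recover the
isometry nulls 3, 1.5, 1 exactly at zero noise. Amplitude constants are
anchored so absolute magnitudes are realistic (e.g. a 100 mm-GMS specimen
carries a middle-ear volume of roughly 6 × 10³ mm³).

Resonator tables carry two apertures per specimen: the tympanum (flanged,
aperture area = tympanum area) and the subtympanic foramen (unflanged,
area ∝ DSL², neck ∝ DSL). In `isometric` mode the cavity volume is the
specimen's middle-ear volume — geometry follows the series' own scaling. In
`frequency_locked` mode the cavity volume is instead solved per aperture,
`V = A c²/(4π² f₀² L)`, to hold the resonance at a target frequency
(defaults 2966 and 1051 Hz, the geometric mid-points of the observed
tympanic and subtympanic bands), then perturbed by the configured noise;
at zero noise the band ratio is exactly 1.

What passing tests on these data show — and do not show. The generator
reproduces the *statistical* structure the analysis assumes (power laws in
GMS, lognormal noise, the printed size range) and so validates the
estimators: slopes, CIs, test calibration, band summaries. It does not
simulate real sinus branching anatomy, segmentation error, left/right
asymmetry, or deviations from power-law growth; phantom volumes are
geometric test objects (spheres/ellipsoids with closed-form metrics), not
anatomical models. Results on synthetic data certify the code, not the
biology.

## Problem sizes and runtime choices

The test suite and acceptance script are sized for a desk run: phantom balls
up to radius 32 voxels (69³ grids), split phantoms of ~81×45×45, growth
series of n = 13 and n = 200, 500 CI-coverage simulations and 2000 slope-test
replicates. The full suite runs in well under a minute; each individual
oracle check completes in seconds. These sizes were chosen because every
oracle comparison is already stable at them (errors far from their
tolerances); larger grids change nothing but the wait.

## Known limitations

- The acoustic model is a single-degree-of-freedom resonator: no tympanic
  membrane mechanics, no columellar load, no interaural (through-head)
  transmission, no damping — it predicts a natural frequency, not a
  transfer function.
- Constriction splitting assumes necks are narrower than lobes in the
  inscribed-sphere sense; gradually tapering spaces without a distance-
  transform saddle will not be cut, and heavily anisotropic voxels blur
  necks thinner than one slice.
- Ellipsoid phantom surface areas use the Thomsen approximation (≤ ~1.1%
  error) and are flagged `approx`; sphere metrics are exact.
- NRRD support covers attached-header raw/gzip integer volumes — the subset
  the pipeline writes and reads — not the full format.
- The measurement-fraction constants of the generator are arbitrary; only
  the exponent and noise structure, not the per-measurement proportions,
  are calibrated to real material.
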