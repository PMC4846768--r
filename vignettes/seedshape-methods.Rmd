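---
title: "Quantifying seed shape: indices, geometric models and the J index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed shape: indices, geometric models and the J index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshape)
```

## The problem

Seed shape carries taxonomic, genetic and agronomic signal: related
genotypes differ in subtle outline features, mutants in hormone signalling
or cell-wall synthesis change seed geometry, and shape interacts with
dispersal and germination. Two complementary quantification strategies are
in routine use:

1. **Scalar descriptors** of a silhouette or of caliper measurements —
   eccentricity index, aspect ratio, flatness index, circularity,
   roundness, rugosity.
2. **Similarity to a geometric model**: the silhouette is superimposed on
   a reference curve (circle, ellipse, cardioid, golden-ratio-stretched
   cardioid, ovoid) and the percentage of shared area, the **J index**, is
   reported. Seeds of *Arabidopsis* and several legumes are classically
   modelled by cardioid-derived figures; Euphorbiaceae by ellipses;
   Asteraceae and Cucurbitaceae by ovoids.

`seedshape` implements both strategies end to end: image in, per-seed CSV
out.

## Scalar indices

With `L`, `W`, `H` the seed length, width and height, `Ps` the silhouette
perimeter, `Pc` its convex perimeter, and area and axes from the
silhouette:

| index | formula | range | notes |
|---|---|---|---|
| eccentricity index | $EI = L/W$ | $\ge 1$ | caliper or bounding-box elongation |
| aspect ratio | $AR = \text{major}/\text{minor}$ | $\ge 1$ | axes of the moment-matched ellipse |
| flatness index | $FI = (L+W)/(2H)$ | $\ge$ ~0.5 | 1 for spheres, $>2$ for spindly seeds |
| circularity | $I = 4\pi A / P_s^2$ | $(0,1]$ | 1 for circles; sensitive to boundary roughness |
| roundness | $R = 4A/(\pi\,\text{major}^2)$ | $(0,1]$ | insensitive to small protuberances; $=b/a$ for ellipses |
| rugosity | $P_s/P_c$ | $\ge 1$ | 1 for convex outlines |

Design points:

* **`H` is never inferred from an image.** The flatness index is 3-D;
  `flatness_index()` and `indices_from_measurements()` only run on
  explicit user-supplied heights.
* **Axes are full diameters** (the particle-analysis convention), so the
  same lengths feed $AR$ and $R$ consistently.
* **L and W come from the minimum-area rotated bounding rectangle**, not
  an axis-aligned box, so they do not depend on how the seed lies in the
  image.
* **Discretization slack.** Circularity and roundness of rasterized
  shapes can exceed their theoretical bound of 1 by a fraction of a
  percent. Values up to $1 + 10^{-3}$ are clamped with a warning; larger
  excesses raise an error, because they signal a genuine upstream bug
  rather than pixelation.
* Circularity uses the raw perimeter (its defining form), not the convex
  one; for seeds with protuberances, roundness is the robust companion.

## Geometric models

All models are sampled polygons (default 720 vertices, uniform in the
parameter angle; area error of the built-ins is below 0.01%).

* **Cardioid** `r = a(1 + cos θ)`: cusp at the origin (always emitted as a
  vertex), lobe at `(2a, 0)`, enclosed area `3πa²/2`. Note a geometric
  subtlety: the cardioid's *bounding box and principal moment axis* are
  transverse to the cusp axis — the curve is wider across than along it.
* **Stretched cardioids** `cardioid_x_phi`, `cardioid_y_phi`: the base
  cardioid elongated about its centroid by the golden ratio
  Φ = (1+√5)/2 ≈ 1.618 along the cusp axis (x) or across it (y). These
  are the classical models for *Arabidopsis* and *Medicago* seeds
  respectively. Elongation about the centroid keeps alignment
  translation-free; the stretch direction convention (x = the cusp axis
  of the base curve) is this package's own and is not claimed to match
  any particular historical software.
* **Ellipse/circle** `(a cos θ, b sin θ)`.
* **Ovoid**: a Hügelschäffer-type egg,
  $x = a\cos\theta,\; y = ab\sin\theta/\sqrt{a^2 + 2wa\cos\theta + w^2}$
  with shift $w = \text{asymmetry}\cdot a$. At `asymmetry = 0` it reduces
  *exactly* (same vertices) to the ellipse; positive asymmetry narrows
  the +x pole. This is the smallest parameterisation that spans the
  ovoid seed outlines of interest; the aspect defaults to Φ.

Model coordinates are dimensionless; physical units enter only through
the image pixel size.

## Silhouette extraction

`binarize()` thresholds dark seeds on a light background (Otsu's
between-class-variance criterion by default, via EBImage), and
`extract_silhouettes()` labels 8-connected components, fills interior
holes (seed silhouettes are solid), rejects specks below `min_area_px`
(default 50 px, which at the recommended ≥ 500 px/seed resolution only
removes dust), and traces each outline.

**Contour convention.** Outlines are traced by marching squares at the
0.5 iso-level with linear interpolation, applied to a Gaussian-smoothed
copy of the mask. The smoothing scale is size-adaptive,
σ = 0.25·√(equivalent radius) px clamped to [1, 6]: raw binary contours
carry an angle-dependent perimeter bias of about +1% (staircase corners),
which would inflate rugosity and deflate circularity; with the adaptive
scale the bias falls with resolution (disk perimeter error is ≈ +0.23%
at 64 px diameter and ≈ −0.001% at 1024 px), giving the monotone
convergence of circularity toward 1 that the tests assert. Because σ
grows much more slowly than feature size, genuine boundary roughness at
the scale of the harmonics used in the fixture generator (and of real
seed lobes) survives smoothing.

Pixel coordinates are converted to y-up mathematical coordinates before
any model comparison, so silhouettes are never chirally flipped relative
to the model curves. Components are returned sorted left-to-right by
centroid (ties top-to-bottom) — a fixed, deterministic order.

`fit_ellipse()` is the moment-matched ellipse: identical second-order
central moments as the polygon region (computed exactly by Green's
theorem), full axes $4\sqrt{\lambda_i}$.

## The J index

For a seed silhouette and a model figure in a common frame,

$$J = \frac{C}{C + D} \times 100,$$

where $C$ is the shared area and $D$ the total unshared area. $J/100$ is
exactly the Jaccard intersection-over-union; $J = 100$ iff the figures
coincide, and $J$ measures *shape*, not size, because alignment fixes the
model scale so the areas are equal.

**Alignment** (`align_model()`): scale set by equal areas; centroids
matched; principal axes aligned. The principal axis leaves a 180°
ambiguity, a mirror ambiguity, and — because the cardioid's moment axis
is transverse to its cusp axis — a genuine axis-swap ambiguity for seeds
elongated along the cusp direction. All are resolved by evaluating J at
eight candidate poses (quarter-turn rotation steps × optional flip) and
keeping the best; ties (symmetry-equivalent poses) resolve
deterministically to the earliest candidate. With `refine = TRUE` a
Nelder-Mead search over (rotation, dx, dy) polishes the pose (≤ 120
iterations, relative tolerance 10⁻⁶). Refinement is the default for
measurements; tests that assert byte-identical reruns turn it off.

**Computation** (`compute_j()`): exact polygon booleans
(intersection, symmetric difference, union) via the Clipper library,
clipping at a spatial resolution of 10⁻¹² times the coordinate magnitude
so that the additivity identity $C + D = \text{area(union)}$ — asserted
on every call — and rigid invariance hold to ~10⁻⁹. An independent
even-odd scanline raster oracle (`raster_j_oracle()`) re-derives J by
pixel counting; the two routes agree within 0.1 J units on the standard
fixture battery at raster resolution 1600.

**Regions** (`regional_j()`): in the aligned frame (seed centroid at the
origin, model reference direction along +x), the global $C$ and $D$
pieces are clipped to left/right halves or quadrants and the J formula is
applied per region; because the pieces are clips of the global regions,
area-weighted recombination reproduces the global J to 10⁻⁶. Conventions
the package fixes (the literature leaves them unstated): the **cusp side
is right** for cardioid models, taken from the curve's construction (not
from moments, whose sign is unstable at ±π/2); **Q1 is the upper-right
quadrant**, numbered counter-clockwise. When the fit needed a mirror
flip, the model appears flipped in the aligned frame and the seed keeps
its own chirality; quadrant labels then refer to the seed as imaged.

**Morphotypes** (`classify_morphotype()`): type A (left ≥ 92 and
right ≥ 80), B (left < 92, right ≥ 80), C (left ≥ 92, right < 80), BC
(both below). Thresholds are the published cardioid defaults and are
exposed as arguments, since other species will need other cutoffs;
threshold values themselves count as "above", so every pair classifies.
The published verbal definition of type BC garbles left/right; the
self-consistent reading (both sides below threshold) is used.

## Synthetic fixtures and what they do (not) show

`generate_seed_image()` renders a model curve whose radius is perturbed
by a smooth random Fourier series (harmonics 2–8, zero-mean, standard
deviation `radial_noise_sigma` × scale — low-frequency because real seed
outlines are smooth; white noise would self-intersect the polygon, and
any draw that does self-intersect is redrawn, up to 10 attempts). The
pose is applied, and the outline is rasterized with 3× supersampled
anti-aliasing as a dark seed (≈ 30) on a light background (255). The
exact perturbed polygon is returned as ground truth. Each fixture owns a
private RNG stream seeded by its spec, so identical specs are
bit-identical and the caller's RNG state is untouched.

Defaults emulate the recommended imaging regime: 500 px across the seed,
high-contrast background, well-separated seeds. Default noise is zero;
the test battery sweeps σ ∈ {0, 0.01, 0.02, 0.03, 0.05}, where σ = 0.01–0.02
visually matches the outline variability of healthy seed lots and σ = 0.05
is strongly deformed. What the fixtures deliberately do **not** emulate:
texture, shadows, uneven illumination, touching seeds, camera distortion.
Passing tests therefore validate the geometry and measurement chain, not
robustness to difficult photography; real images should be checked via
the diagnostic columns (threshold, fit parameters) in the run log.

Problem sizes used by the test battery (chosen to exercise every claim
at desk scale): model convergence at 10⁵ vertices; oracle equivalence on
50 seeded fixtures at raster resolution 1600; pipeline noise sweep on
20 seeds per σ at generator resolution 300; self-recovery on 20 random
rigid poses.

## Numerical choices and degenerate inputs

* Polygons are stored counter-clockwise; clockwise input is reversed on
  construction; zero-area or < 3-vertex chains are rejected.
* Simplicity is checked by a brute-force O(n²) segment-intersection test
  on public `compute_j()` calls; alignment loops skip it (their inputs
  were already validated).
* Constant images without an explicit threshold, empty label sets,
  collinear regions, zero axes and out-of-range index inputs all raise
  typed errors rather than propagating NaN.
* Ties at morphotype thresholds resolve "above"; ties among alignment
  candidate poses resolve to the unflipped, least-rotated candidate.
* `run_measure()` with `refine = FALSE` is fully deterministic: reruns
  produce byte-identical CSVs (numeric fields at 6 significant digits,
  `.` decimal separator regardless of locale).

## Known limitations

* 2-D only: no ellipsoid/pyramid solids; FI requires measured heights.
* One model per run; no automatic model selection.
* No separation of touching seeds (no watershed) and no colour-based
  segmentation.
* Elliptic Fourier outline descriptors are out of scope.
* J comparisons against published values for real seed lots require the
  original images, which are not distributed; the package's accuracy
  claims rest on ground-truthed synthetic fixtures and analytic shapes.
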