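---
title: "Geometric confinement of actin filaments in micropattern-deformed GUVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric confinement of actin filaments in micropattern-deformed GUVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvconfine)
```

## The scientific problem

Giant unilamellar vesicles (GUVs) adhering to adhesive micropatterns —
stripes, crosses, crossbows, circles — deform so that their cross-section
near the surface adopts the pattern's footprint. When actin filaments are
encapsulated, the deformed membrane acts as a rigid two-dimensional
confinement at the analysis plane, and filament orientation becomes a pure
geometry problem: a rigid rod of length $L$ can only occupy positions and
orientations where it fits entirely inside the cross-section contour.

`guvconfine` implements this confinement model together with the image
analysis needed to feed it (plane selection, contour extraction, axis
measurement), the traced-filament orientation pipeline, deformation
statistics, and a seeded synthetic-data generator that provides ground
truth for every stage.

## The confinement model

**Assumptions.** Filaments are perfectly rigid straight segments; the
boundary is rigid; every placement that fits is equally likely (no bending
energetics, no filament–filament interactions, no Boltzmann weighting).
Touching the boundary is allowed: the contour confines but does not repel.

**Enumeration.** For a contour with moment-based major-axis length $M$
(pixels) and a length fraction $f \in (0, 1]$, the filament length is
$L = f M$. Candidate midpoints live on a square grid of spacing
`grid_step` (default $M/100$) anchored at the contour's bounding box;
candidate orientations on a grid of spacing `angle_step` (default 1°).
A placement is kept when the centred segment passes an exact containment
test: both endpoints inside (boundary inclusive) and no proper crossing of
any polygon edge, with three interior guard points to catch symmetric
exits through a vertex. The enumeration is deterministic; bit-identical
inputs give bit-identical placement sets.

**Angle grid.** Orientations are *cell-centred*,
$\theta_k = (k + \tfrac12)\,\Delta\theta$. Orientations of unpolarized
filaments are axes: $\theta$, $\theta + 180°$ and $180° - \theta$ are
indistinguishable under the mirror symmetry of the shapes, so angles are
folded as $\theta_f = \min(\phi, 180° - \phi)$ with
$\phi = (\theta - \theta_{\mathrm{ref}}) \bmod 180°$. Cell-centring
avoids the double-counting of $\theta = 0 \equiv 180°$ that an
edge-anchored grid would introduce under folding, and keeps each
histogram bin populated by exactly the same number of grid orientations.
A filament exactly perpendicular to the reference axis folds to exactly
90°, which falls in the closed top bin.

**Histogram convention.** Angle bins over $[0°, 90°]$ are right-closed,
$(\mathrm{lo}, \mathrm{hi}]$, with 0 kept in the first bin; 18 bins of 5°
by default. Probabilities are normalized to sum to 1.

**Heat maps.** Each valid placement deposits weight 1 on every pixel its
rasterized body covers (sampling the segment at 0.5 px and rounding to
pixel centres), so a pixel's value is proportional to the number of
filaments passing through it — where actin material would be found. The
accumulated array is clipped to the contour's interior and divided by its
total, so it sums to 1 over the whole image. A `density = "midpoint"`
variant counts midpoints only; coverage is the default because the
density of interest is material density, not midpoint density.

**Angular distributions** are computed on the contour aligned to its
major axis, so angles are measured relative to the shape's long axis
rather than the image frame (the frame of reference is not fixed by the
experimental setup; the major axis is the natural intrinsic choice).

```{r model-demo}
ct <- synth_guv_contour(synth_guv_spec(pattern_spec("stripe"),
                                       guv_diameter = 15))
d <- angular_distribution(ct, model_config(length_fraction = 0.9))
round(d$probabilities, 3)
```

Short filaments sample the confinement almost uniformly; as $f \to 1$ the
distribution concentrates along the major axis for elongated shapes,
while a circle stays uniform at every length. For a rectangle of width
$w$ the support is bounded in closed form by $\arcsin(w/L)$, one of the
model's exact checks.

## The Monte-Carlo oracle

`sample_placements_mc()` is a deliberately independent route to the same
distribution: uniform random midpoints in the bounding box, uniform
random orientations, and acceptance when `containment_samples` (default
25) points along the body all lie inside the contour. Batches are drawn
under a fixed seed until `n` placements (default $10^5$) have been
accepted — `n` is the Monte-Carlo sample size, so the comparison noise
scales as $n^{-1/2}$ regardless of the acceptance rate. Grid and sampler
agree to total variation distance $\approx 0.005$ on the shapes used
here, against a test tolerance of 0.02.

## Image analysis

The pattern surface is the z-slice with the highest *summed*
pattern-channel intensity (summation resists hot pixels); the analysis
plane lies 2 µm above it, rounded to the nearest slice, since a physical
offset cannot be honoured sub-slice. Contour extraction is Gaussian
smoothing (σ = 1 px), global Otsu threshold, hole filling, largest
connected component, and a sub-pixel marching-squares boundary, decimated
(to ≤ 240 vertices, coarsening further if needed) until the polygon is
simple. These segmentation choices are validated against synthetic ground
truth only: mean boundary error stays under 2 px for noise up to 10% of
peak intensity, and axis ratios are recovered within 5%.

Axis measurement fits the ellipse with the same normalized second central
moments as the filled polygon (computed exactly from the polygon by
Green's theorem, not from a rasterization). This is the common
image-analysis "fit ellipse" convention and is robust to boundary noise;
a maximum-caliper (Feret) alternative is available via
`measure_axes(method = "feret")`. Coordinates are 0-based pixels, x
rightward, y downward; angles in degrees from +x, reduced to [0°, 180°).

## Filament traces

Snake files are parsed as whitespace-separated
`snake_id point_index x y z intensity` rows (header lines and unknown
extra columns ignored, malformed lines reported with line numbers,
single-point snakes skipped). Each trace's orientation is the first
principal axis of its point covariance; the anisotropy (first/second
principal variance) flags near-isotropic traces that do not define a
meaningful axis. Pooling across GUVs is filament-weighted: every filament
counts equally regardless of its vesicle of origin.

## Deformation statistics

Axis ratios are grouped by major-axis length into half-open bins
[5,10), [10,15), [15,20), [20,25), [25,∞) µm — the stated group labels
overlap at their edges, so a lower-closed convention was fixed — and
compared against the smallest-size group with the classical
equal-variance unpaired two-sample t test (two-tailed); Welch's variant
is available via a flag since the equal-variance assumption is a choice,
not a given.

## The synthetic-data generator

The generator emulates the study conditions: stripe patterns 15 µm long
and 5 µm wide, compact patterns 10–20 µm across, 0.1 µm/px so a 20 µm
shape spans 200 px, membrane rings blurred with σ = 2 px, additive
Gaussian noise up to 10% of peak, z-stacks with 0.5 µm spacing whose
pattern channel peaks at the bottom slice.

The deformed analysis-plane contour is a *phenomenological*
interpolation, not a membrane-energy minimizer: in polar coordinates
about the pattern centroid,
$r(\varphi) = (1 - w)\,R + w\,r_{\mathrm{pat}}(\varphi)$, where $R$ is
the free GUV radius, $r_{\mathrm{pat}}$ the pattern silhouette's radius,
and $w = s \exp\!\big(-\log^2(d / d_0) / (2 \sigma^2)\big)$ a log-normal
bump in the GUV diameter $d$ around the pattern size $d_0$ with width
$\sigma = 0.4$. This reproduces the observed size dependence: GUVs much
smaller than the pattern adhere symmetrically, GUVs much larger than it
are barely perturbed, and intermediate ones elongate most. The
per-pattern strength $s$ is 0.5 for stripes (ratio ≈ 1.6 at
$d = d_0$), 0.15 for cross and crossbow, and 0 for circles — compact
patterns constrain the footprint nearly isotropically, so their GUVs
stay close to circular, which is also what makes their sub-0.85 angular
distributions nearly uniform while the stripe's is strongly anisotropic.
The crossbow is parameterized as a three-quarter arc (opening
downward) of the pattern's diameter plus a straight bar closing the
chord, both of the stripe width; only overall widths are specified
externally, so the arc/bar proportions are fixed defaults here.

What the generator does *not* emulate: Poisson/photon statistics
(additive Gaussian noise only), point-spread-function anisotropy in z,
membrane fluctuations, photobleaching, tracing failures (synthetic traces
are jittered polylines, not active-contour output), and any real membrane
mechanics. Passing tests therefore demonstrate that the analysis recovers
known ground truth under idealized imaging, not that segmentation or
tracing would be robust on arbitrary experimental data.

## Numerical choices and degenerate inputs

* Containment treats boundary points as inside; rejecting them would
  discard valid boundary-touching filaments at grid resolution for no
  physical reason.
* Geometric predicates run in compiled code with tolerances scaled to the
  polygon's bounding-box diagonal ($10^{-9}$ relative); polygon validity
  (≥ 3 vertices, simplicity, positive area) is a hard constructor error.
* Heat maps raise a dedicated no-placement condition when the filament
  fits nowhere, distinct from invalid-contour errors; length sweeps flag
  such fractions instead of failing.
* Normalization identities (heat-map total, histogram sums) hold to
  $10^{-9}$, limited only by floating-point summation.
* Ties: an angle folding exactly to 90° lands in the closed top bin; a
  major-axis length exactly at a size-group edge belongs to the upper
  (lower-closed) group.

## Problem sizes

The shipped tests and the acceptance script run at the sizes a desk
machine handles comfortably: contours of 90–240 vertices, midpoint grids
of $\sim 10^2 \times 10^2$, 180 orientations, Monte-Carlo samples of
$10^5$ accepted placements, 1000 synthetic filaments, and image frames up
to $\sim 400^2$ px. These resolve every distribution used here — the
default grid agrees with a 4× finer one to total variation $10^{-3}$.

## Known limitations

The model is strictly two-dimensional and rigid: semiflexible polymers,
bundling and 3D confinement are out of scope. The experimental pipeline
analyzes one vesicle per field (the largest component); the tracing
algorithm itself is external, and the parser makes no attempt to validate
tracer physics beyond geometry. The deformation generator is descriptive;
it cannot be used to infer adhesion energetics.
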