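# guvconfine

Quantitative analysis of how adhesive micropatterns shape giant
unilamellar vesicles (GUVs) and how the resulting two-dimensional
confinement organizes encapsulated actin filaments. The package is aimed
at synthetic-cell and cytoskeleton researchers who image GUVs adhering to
patterned surfaces (stripes, crosses, crossbows, circles) and want to
compare measured filament orientations against a parameter-free geometric
prediction.

## The model

At the analysis plane (2 µm above the pattern surface) the deformed
membrane cross-section is a rigid planar contour. A rigid actin filament
of length *L* = *f* · *M* (a fraction *f* of the contour's major-axis
length *M*) can occupy exactly those placements — midpoint **m**,
orientation θ — whose segment lies entirely inside the contour. Weighting
all valid placements equally gives

- a **heat map**: the probability density of filament material on the
  pixel grid, normalized to 1 over the whole image;
- an **angular distribution**: placement orientations measured from the
  contour's major axis and folded into [0°, 90°] by mirror symmetry,
  θ_f = min(φ, 180° − φ), binned over 18 right-closed 5° bins;
- a **length sweep**: the same distribution for *f* from 0.05 to 0.95.

Short filaments orient uniformly; filaments approaching the major-axis
length align with it — except inside circles, which stay uniform at every
length. For a rectangle of width *w*, folded angles are bounded by
arcsin(*w*/*L*) in closed form.

Around the model, the package provides the full pipeline: z-stack plane
selection and contour extraction (Otsu + marching squares),
equivalent-ellipse axis measurement, a snake-file parser with
principal-component filament orientations, deformation statistics (size
groups, unpaired two-sample tests), a seeded synthetic-data generator
with ground truth, and a command-line interface
(`inst/scripts/guvconfine`).

## Worked example

```r
library(guvconfine)

# A synthetic GUV (diameter 15 um) deformed on a 15 x 5 um stripe pattern
spec    <- synth_guv_spec(pattern_spec("stripe"), guv_diameter = 15)
contour <- synth_guv_contour(spec)
measure_axes(contour)
#> axes: major 15.37 um, minor 9.602 um, ratio 1.601, angle 5.684e-14 deg

# Confinement model at 0.90 x major axis
hm <- heat_map(contour, model_config(length_fraction = 0.9))
hm$total
#> [1] 1

d <- angular_distribution(contour, model_config(0.9))
round(d$probabilities[1:6], 3)
#> [1] 0.343 0.285 0.215 0.129 0.028 0.000
```

The axis ratio 1.6 says the adhered vesicle is strongly elongated; the
heat-map total confirms the density is normalized over the image; and the
angular distribution shows ~97% of all valid placements of a
0.9-length filament lying within 20° of the stripe axis, with no mass
beyond 30° — the geometric origin of actin alignment on stripe patterns.

The experimental route mirrors this on traced filaments:

```r
f <- tempfile()
invisible(synth_filaments(synth_filament_spec(contour, 0.9,
                                              n_filaments = 1000,
                                              seed = 55), path = f))
traces <- parse_snake_file(f)
ref    <- measure_axes(contour)$major_angle
angles <- vapply(traces, function(tr)
  filament_angle(tr, reference_angle = ref)$angle, numeric(1))
ks_distance(experimental_distribution(angles), d)
#> [1] 0.01100548
```

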