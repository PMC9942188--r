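Package: guvconfine
Title: Shape-Controlled Actin Organization in Adherent Giant Unilamellar
    Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how adhesive micropatterns deform giant unilamellar
    vesicles (GUVs) and how the resulting two-dimensional confinement
    organizes encapsulated actin filaments. Implements a rigid-filament
    confinement model that enumerates every position and orientation of a
    straight filament inside an arbitrary planar contour and derives
    normalized probability-density heat maps and folded angular
    distributions, including filament-length sweeps. Companion image
    analysis selects the analysis plane of multi-channel z-stacks, extracts
    GUV contours by thresholding and marching squares, and measures
    equivalent-ellipse major/minor axes; traced-filament files are parsed
    and per-filament orientations obtained by principal component analysis.
    Deformation statistics (axis ratios, size groups, unpaired two-sample
    tests) and a fully seeded synthetic-data generator with known ground
    truth complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
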