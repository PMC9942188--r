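# Synthetic inputs with known ground truth: micropattern masks, deformed
# GUV contours, membrane-ring images and z-stacks, and filament traces
# drawn from the confinement model. Everything is deterministic under a
# fixed seed.
#
# The deformation generator is phenomenological: the analysis-plane
# contour interpolates, in polar coordinates about the pattern centroid,
# between a circle of the GUV's diameter and the pattern silhouette. The
# blend weight is a log-normal bump in guv_diameter / pattern_size, so
# GUVs much smaller or much larger than the pattern stay near-circular and
# intermediate ones elongate — the size dependence observed for adherent
# vesicles. Per-pattern strengths reflect that only the stripe imposes a
# strong uniaxial constraint; compact patterns (cross, crossbow) leave the
# vesicle near-circular.

DEFORM_STRENGTH <- c(stripe = 0.5, cross = 0.15, crossbow = 0.15, circle = 0)
DEFORM_SIGMA_LOG <- 0.4

#' Specify an adhesive micropattern
#'
#' @param kind `"stripe"`, `"cross"`, `"crossbow"` or `"circle"`.
#' @param size characteristic size in micrometres: stripe/cross length
#'   (default 15) or crossbow/circle diameter.
#' @param stripe_width stripe (and cross-arm, crossbow-bar) width in
#'   micrometres; default 5.
#' @param pixel_size micrometres per pixel; default 0.1.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(kind = c("stripe", "cross", "crossbow", "circle"),
                         size = 15, stripe_width = 5, pixel_size = 0.1) {
  kind <- match.arg(kind)
  if (size <= 0 || stripe_width <= 0 || pixel_size <= 0)
    stop_invalid_input("size, stripe_width and pixel_size must be positive")
  if (kind %in% c("stripe", "cross") && stripe_width >= size)
    stop_invalid_input("stripe_width must be smaller than size")
  if (min(size, stripe_width) / pixel_size < 10)
    stop_invalid_input("resolution too coarse: shape under 10 px across")
  structure(list(kind = kind, size = size, stripe_width = stripe_width,
                 pixel_size = pixel_size),
            class = "pattern_spec")
}

# silhouette polygon (px, centred at `center`) of the filled pattern
pattern_silhouette <- function(spec, center = c(0, 0)) {
  L <- spec$size / spec$pixel_size
  w <- spec$stripe_width / spec$pixel_size
  pts <- switch(spec$kind,
    stripe = {
      l <- L / 2; h <- w / 2
      cbind(c(-l, l, l, -l), c(-h, -h, h, h))
    },
    cross = {
      l <- L / 2; h <- w / 2
      cbind(c(-l, -h, -h, h, h, l, l, h, h, -h, -h, -l),
            c(-h, -h, -l, -l, -h, -h, h, h, l, l, h, h))
    },
    circle = ellipse_points(L / 2, L / 2, n = 120),
    crossbow = {
      R <- L / 2
      th <- seq(-45, 225, by = 3) * pi / 180
      arc <- cbind(R * cos(th), R * sin(th))
      y0 <- -R / sqrt(2)
      rbind(arc,
            c(-R / sqrt(2), y0 - w), c(R / sqrt(2), y0 - w))
    })
  sweep(pts, 2, center, "+")
}

# logical [x, y] mask of the pattern's adhesive area (the crossbow keeps
# its open arc + bar geometry; the silhouette above is the filled outline)
pattern_pixels <- function(spec, center, dims) {
  px <- rep(seq_len(dims[1]) - 1, times = dims[2])
  py <- rep(seq_len(dims[2]) - 1, each = dims[1])
  dx <- px - center[1]; dy <- py - center[2]
  L <- spec$size / spec$pixel_size
  w <- spec$stripe_width / spec$pixel_size
  # half-open pixel-centre coverage so an L-wide feature spans exactly
  # L pixels
  inb <- function(v, halfwidth) v >= -halfwidth & v < halfwidth
  on <- switch(spec$kind,
    stripe = inb(dx, L / 2) & inb(dy, w / 2),
    cross = (inb(dx, L / 2) & inb(dy, w / 2)) |
      (inb(dy, L / 2) & inb(dx, w / 2)),
    circle = dx^2 + dy^2 <= (L / 2)^2,
    crossbow = {
      R <- L / 2
      r <- sqrt(dx^2 + dy^2)
      ang <- (atan2(dy, dx) * 180 / pi) %% 360
      arc <- r <= R & r >= R - w & (ang <= 225 | ang >= 315)
      y0 <- -R / sqrt(2)
      bar <- abs(dx) <= R / sqrt(2) & dy <= y0 & dy >= y0 - w
      arc | bar
    })
  matrix(on, nrow = dims[1], ncol = dims[2])
}

#' Rasterize a micropattern mask
#'
#' @param spec a [pattern_spec()].
#' @param margin_px margin of background pixels around the shape.
#' @return List with `mask` (logical matrix \[x, y\]), `contour` (the
#'   filled-silhouette [shape_contour()]) and `center` (px).
#' @export
make_pattern_mask <- function(spec, margin_px = 10) {
  if (!inherits(spec, "pattern_spec"))
    stop_invalid_input("expected a 'pattern_spec'")
  sil <- pattern_silhouette(spec)
  ext <- apply(sil, 2, range)
  dims <- c(ceiling(diff(ext[, 1])) + 2 * margin_px + 1,
            ceiling(diff(ext[, 2])) + 2 * margin_px + 1)
  center <- c((dims[1] - 1) / 2, (dims[2] - 1) / 2)
  mask <- pattern_pixels(spec, center, dims)
  contour <- shape_contour(pattern_silhouette(spec, center),
                           spec$pixel_size, spec$kind)
  list(mask = mask, contour = contour, center = center)
}

#' Specify a synthetic adherent GUV
#'
#' @param pattern a [pattern_spec()].
#' @param guv_diameter free GUV diameter in micrometres.
#' @param membrane_sigma Gaussian blur of the membrane ring, pixels.
#' @param noise_sigma additive Gaussian noise, as a fraction of the peak
#'   intensity.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A `synth_guv_spec` list.
#' @export
synth_guv_spec <- function(pattern, guv_diameter, membrane_sigma = 2,
                           noise_sigma = 0.05, seed = 1) {
  if (!inherits(pattern, "pattern_spec"))
    stop_invalid_input("pattern must be a 'pattern_spec'")
  if (guv_diameter <= 0) stop_invalid_input("guv_diameter must be positive")
  if (noise_sigma < 0) stop_invalid_input("noise_sigma must be >= 0")
  structure(list(pattern = pattern, guv_diameter = guv_diameter,
                 membrane_sigma = membrane_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_guv_spec")
}

# polar radius of a star-shaped polygon about `origin`, by ray casting
polar_radius <- function(pts, origin, phis) {
  n <- nrow(pts)
  ax <- pts[, 1] - origin[1]; ay <- pts[, 2] - origin[2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  vapply(phis, function(phi) {
    dx <- cos(phi); dy <- sin(phi)
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    t <- (ax * ey - ay * ex) / den          # distance along the ray
    u <- (ax * dy - ay * dx) / den          # position along the edge
    hit <- ok & t > 0 & u >= -1e-9 & u <= 1 + 1e-9
    if (!any(hit)) 0 else max(t[hit])
  }, numeric(1))
}

deform_weight <- function(spec) {
  s <- DEFORM_STRENGTH[[spec$pattern$kind]]
  s * exp(-log(spec$guv_diameter / spec$pattern$size)^2 /
            (2 * DEFORM_SIGMA_LOG^2))
}

#' Ground-truth analysis-plane contour of a synthetic adherent GUV
#'
#' Polar interpolation between a circle of the GUV's diameter and the
#' pattern silhouette; the blend weight peaks when the GUV diameter
#' matches the pattern size, so very small and very large GUVs are
#' near-circular and intermediate ones are elongated.
#'
#' @param spec a [synth_guv_spec()].
#' @param n_vertices number of contour vertices.
#' @param center contour centre in px; default places the shape in a
#'   padded frame.
#' @return A [shape_contour()] labelled by pattern kind.
#' @export
synth_guv_contour <- function(spec, n_vertices = 180, center = NULL) {
  if (!inherits(spec, "synth_guv_spec"))
    stop_invalid_input("expected a 'synth_guv_spec'")
  pat <- spec$pattern
  R <- spec$guv_diameter / 2 / pat$pixel_size
  w <- deform_weight(spec)
  phis <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  sil <- pattern_silhouette(pat)
  ctr0 <- contour_centroid(sil)
  rpat <- polar_radius(sil, ctr0, phis)
  r <- (1 - w) * R + w * rpat
  if (is.null(center)) center <- rep(ceiling(max(r)) + 10, 2)
  shape_contour(cbind(center[1] + r * cos(phis), center[2] + r * sin(phis)),
                pat$pixel_size, pat$kind)
}

# paint a thin ring along a closed polyline onto a [x, y] canvas
paint_ring <- function(pts, dims) {
  canvas <- matrix(0, dims[1], dims[2])
  closed <- rbind(pts, pts[1, ])
  seg <- diff(closed)
  len <- sqrt(rowSums(seg^2))
  for (i in seq_len(nrow(seg))) {
    n <- max(2L, ceiling(len[i] / 0.3))
    t <- seq(0, 1, length.out = n)
    xs <- round(closed[i, 1] + t * seg[i, 1]) + 1
    ys <- round(closed[i, 2] + t * seg[i, 2]) + 1
    ok <- xs >= 1 & xs <= dims[1] & ys >= 1 & ys <= dims[2]
    canvas[cbind(xs[ok], ys[ok])] <- 1
  }
  canvas
}

blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.array(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Synthesize a two-channel image of an adherent GUV
#'
#' Membrane channel: the ground-truth contour rasterized as a thin ring,
#' Gaussian-blurred and overlaid with seeded additive Gaussian noise
#' (clamped to \[0, 1\]). Pattern channel: the blurred pattern mask.
#'
#' @param spec a [synth_guv_spec()].
#' @param margin_px background margin around the larger of GUV and
#'   pattern.
#' @return A `synth_image`: list with `channels` (named matrices
#'   `membrane`, `pattern`), the ground-truth `contour`, `pixel_size` and
#'   `spec`.
#' @export
synth_image <- function(spec, margin_px = 12) {
  if (!inherits(spec, "synth_guv_spec"))
    stop_invalid_input("expected a 'synth_guv_spec'")
  pat <- spec$pattern
  R <- spec$guv_diameter / 2 / pat$pixel_size
  ext <- max(R, pat$size / pat$pixel_size / 2)
  half <- ceiling(ext) + margin_px
  dims <- c(2 * half + 1, 2 * half + 1)
  center <- c(half, half)
  contour <- synth_guv_contour(spec, center = center)
  ring <- blur_mat(paint_ring(contour$points, dims), spec$membrane_sigma)
  if (max(ring) > 0) ring <- ring / max(ring)
  membrane <- with_seed(spec$seed, {
    noisy <- ring + rnorm(length(ring), sd = spec$noise_sigma)
    matrix(pmin(pmax(noisy, 0), 1), dims[1], dims[2])
  })
  pattern <- blur_mat(pattern_pixels(pat, center, dims) + 0, 1)
  structure(list(channels = list(membrane = membrane, pattern = pattern),
                 contour = contour, pixel_size = pat$pixel_size,
                 spec = spec),
            class = "synth_image")
}

#' Synthesize a two-channel z-stack of an adherent GUV
#'
#' The per-slice membrane contour interpolates from the pattern-adapted
#' analysis-plane shape at the bottom to a shrinking near-circular cap at
#' the top (widest slice near the bottom, areas monotonically decreasing
#' above it); the pattern channel peaks at the bottom slice.
#'
#' @param spec a [synth_guv_spec()].
#' @param n_slices number of slices (>= 3).
#' @param z_spacing slice spacing in micrometres.
#' @param margin_px background margin.
#' @return List with `stack` (a [z_stack()]), `contours` (ground-truth
#'   [shape_contour()] per slice) and `spec`.
#' @export
synth_zstack <- function(spec, n_slices = 9, z_spacing = 0.5,
                         margin_px = 12) {
  if (!inherits(spec, "synth_guv_spec"))
    stop_invalid_input("expected a 'synth_guv_spec'")
  if (n_slices < 3) stop_invalid_input("n_slices must be >= 3")
  pat <- spec$pattern
  R <- spec$guv_diameter / 2 / pat$pixel_size
  ext <- max(R, pat$size / pat$pixel_size / 2)
  half <- ceiling(ext) + margin_px
  dims <- c(2 * half + 1, 2 * half + 1)
  center <- c(half, half)
  w0 <- deform_weight(spec)
  phis <- seq(0, 2 * pi, length.out = 181)[-181]
  sil <- pattern_silhouette(pat)
  rpat <- polar_radius(sil, contour_centroid(sil), phis)
  membrane <- array(0, dim = c(dims, n_slices))
  pattern <- array(0, dim = c(dims, n_slices))
  contours <- vector("list", n_slices)
  pat_mask <- blur_mat(pattern_pixels(pat, center, dims) + 0, 1)
  widest <- 0.2  # widest slice sits just above the adhesion plane
  for (i in seq_len(n_slices)) {
    zf <- (i - 1) / (n_slices - 1)
    m <- sqrt(max(0.02, 1 - ((zf - widest) / 0.85)^2))
    wz <- w0 * (1 - zf)
    r <- m * ((1 - wz) * R + wz * rpat)
    ct <- shape_contour(cbind(center[1] + r * cos(phis),
                              center[2] + r * sin(phis)),
                        pat$pixel_size, sprintf("%s_z%d", pat$kind, i))
    contours[[i]] <- ct
    ring <- blur_mat(paint_ring(ct$points, dims), spec$membrane_sigma)
    if (max(ring) > 0) ring <- ring / max(ring)
    membrane[, , i] <- ring
    pattern[, , i] <- pat_mask * exp(-((i - 1) * z_spacing / 1.0)^2)
  }
  membrane <- with_seed(spec$seed, {
    noisy <- membrane + rnorm(length(membrane), sd = spec$noise_sigma)
    array(pmin(pmax(noisy, 0), 1), dim = dim(membrane))
  })
  list(stack = z_stack(list(membrane = membrane, pattern = pattern),
                       z_spacing = z_spacing, pixel_size = pat$pixel_size),
       contours = contours, spec = spec)
}

#' Specify synthetic filament traces
#'
#' @param contour the confining [shape_contour()].
#' @param length_fraction filament length as a fraction of the major axis.
#' @param n_filaments number of traces to draw.
#' @param jitter_sigma isotropic Gaussian jitter of trace points, pixels.
#' @param points_per_filament points per trace (>= 2).
#' @param seed integer seed.
#' @return A `synth_filament_spec` list.
#' @export
synth_filament_spec <- function(contour, length_fraction = 0.9,
                                n_filaments = 100, jitter_sigma = 0.5,
                                points_per_filament = 10, seed = 1) {
  assert_contour(contour)
  if (points_per_filament < 2)
    stop_invalid_input("points_per_filament must be >= 2")
  if (n_filaments < 1) stop_invalid_input("n_filaments must be >= 1")
  if (jitter_sigma < 0) stop_invalid_input("jitter_sigma must be >= 0")
  structure(list(contour = contour, length_fraction = length_fraction,
                 n_filaments = n_filaments, jitter_sigma = jitter_sigma,
                 points_per_filament = as.integer(points_per_filament),
                 seed = as.integer(seed)),
            class = "synth_filament_spec")
}

#' Draw synthetic filament traces from the confinement model
#'
#' Samples placements uniformly (seeded) from the model's enumeration,
#' turns each into an ordered polyline with isotropic Gaussian jitter, and
#' optionally writes the traces in the snake dialect.
#'
#' @param spec a [synth_filament_spec()].
#' @param config optional [model_config()]; `length_fraction` is taken
#'   from `spec`.
#' @param path optional path for a snake-dialect file.
#' @return List with `traces` (list of [filament_trace()]),
#'   `true_angles` (folded ground-truth angles relative to the contour's
#'   major axis) and `placements` (sampled rows).
#' @export
synth_filaments <- function(spec, config = NULL, path = NULL) {
  if (!inherits(spec, "synth_filament_spec"))
    stop_invalid_input("expected a 'synth_filament_spec'")
  if (is.null(config)) config <- model_config(spec$length_fraction)
  config$length_fraction <- spec$length_fraction
  ps <- enumerate_placements(spec$contour, config)
  if (nrow(ps$placements) == 0)
    stop_no_placement("confinement model admits no placement at this length")
  ref <- ps$axes$major_angle
  with_seed(spec$seed, {
    rows <- sample.int(nrow(ps$placements), spec$n_filaments, replace = TRUE)
    pl <- ps$placements[rows, , drop = FALSE]
    t <- seq(-0.5, 0.5, length.out = spec$points_per_filament)
    traces <- vector("list", spec$n_filaments)
    for (i in seq_len(spec$n_filaments)) {
      th <- pl$angle_deg[i] * pi / 180
      xs <- pl$mid_x[i] + t * ps$length_px * cos(th) +
        rnorm(length(t), sd = spec$jitter_sigma)
      ys <- pl$mid_y[i] + t * ps$length_px * sin(th) +
        rnorm(length(t), sd = spec$jitter_sigma)
      traces[[i]] <- filament_trace(i, cbind(xs, ys))
    }
    out <- list(traces = traces,
                true_angles = fold_angle(pl$angle_deg, ref),
                placements = pl)
    if (!is.null(path)) write_snake_file(traces, path)
    out
  })
}
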