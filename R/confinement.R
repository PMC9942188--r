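# Rigid-filament confinement model: enumerate every placement (midpoint on
# a grid, orientation on an angle grid) of a straight filament of fixed
# length that fits entirely inside a planar contour, and summarize the
# placements as probability-density heat maps and folded angular
# distributions.
#
# Placements are weighted uniformly: filaments are perfectly rigid straight
# lines and their distribution is governed by the confinement alone, with no
# bending or interaction energetics.

#' Configuration for the confinement model
#'
#' @param length_fraction filament length in units of the contour's
#'   major-axis length, in (0, 1].
#' @param grid_step spacing of candidate midpoints in pixels; default
#'   (`NULL`) resolves to major_length / 100 at evaluation time.
#' @param angle_step orientation grid spacing in degrees; must divide 180.
#'   Candidate angles are cell-centred, `(k + 1/2) * angle_step`, which
#'   balances the folded histogram and avoids double-counting the 0/180
#'   identification.
#' @param containment_samples number of points tested along a segment by
#'   the Monte-Carlo rejection sampler ([sample_placements_mc()]); the grid
#'   enumeration itself uses exact edge-crossing tests and ignores this.
#' @param density `"coverage"` deposits heat-map weight on every pixel a
#'   filament body covers (where actin material would be found);
#'   `"midpoint"` counts midpoints only.
#' @return A `model_config` list.
#' @export
model_config <- function(length_fraction = 0.9, grid_step = NULL,
                         angle_step = 1, containment_samples = 25,
                         density = c("coverage", "midpoint")) {
  density <- match.arg(density)
  if (!is.numeric(length_fraction) || length_fraction <= 0 ||
      length_fraction > 1)
    stop_invalid_input("length_fraction must be in (0, 1]")
  if (!is.null(grid_step) && (!is.numeric(grid_step) || grid_step <= 0))
    stop_invalid_input("grid_step must be positive")
  if (!is.numeric(angle_step) || angle_step <= 0 ||
      abs(180 / angle_step - round(180 / angle_step)) > 1e-9)
    stop_invalid_input("angle_step must be positive and divide 180")
  if (!is.numeric(containment_samples) || containment_samples < 2)
    stop_invalid_input("containment_samples must be >= 2")
  structure(list(length_fraction = length_fraction, grid_step = grid_step,
                 angle_step = angle_step,
                 containment_samples = as.integer(containment_samples),
                 density = density),
            class = "model_config")
}

assert_config <- function(config) {
  if (!inherits(config, "model_config"))
    stop_invalid_input("expected a 'model_config' object")
  invisible(config)
}

# resolve grid step and filament length (px) for a given contour
resolve_config <- function(contour, config) {
  ax <- measure_axes(contour)
  major_px <- ax$major_length / contour$pixel_size
  minor_px <- ax$minor_length / contour$pixel_size
  gs <- if (is.null(config$grid_step)) major_px / 100 else config$grid_step
  if (gs > minor_px / 4)
    warning("grid_step exceeds minor_length/4; placements may be undersampled")
  list(grid_step = gs, length_px = config$length_fraction * major_px,
       axes = ax)
}

model_angles <- function(angle_step) {
  (seq_len(round(180 / angle_step)) - 0.5) * angle_step
}

#' Enumerate all valid filament placements inside a contour
#'
#' Tests the filament of length `length_fraction * major_length`, centred
#' at every grid midpoint and oriented at every grid angle, for full
#' containment in the contour ([segment_inside()]). Deterministic for fixed
#' inputs; an empty result (filament too long for the shape) is returned as
#' an empty set, not an error.
#'
#' @param contour a [shape_contour()].
#' @param config a [model_config()].
#' @return A `placement_set`: list with `placements` (data frame of
#'   `mid_x`, `mid_y`, `angle_deg`), `length_px`, `grid_step`,
#'   `angle_step`, `length_fraction` and `axes`.
#' @export
enumerate_placements <- function(contour, config = model_config()) {
  assert_contour(contour)
  assert_config(config)
  rs <- resolve_config(contour, config)
  pts <- contour$points
  gx <- seq(min(pts[, 1]), max(pts[, 1]), by = rs$grid_step)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), by = rs$grid_step)
  gr <- expand.grid(x = gx, y = gy)
  keep <- points_in_polygon_cpp(gr$x, gr$y, pts[, 1], pts[, 2])
  gr <- gr[keep, , drop = FALSE]
  angles <- model_angles(config$angle_step)
  half <- rs$length_px / 2
  res <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    dx <- half * cos(th); dy <- half * sin(th)
    ok <- segments_inside_cpp(gr$x - dx, gr$y - dy, gr$x + dx, gr$y + dy,
                              pts[, 1], pts[, 2])
    if (any(ok))
      res[[i]] <- data.frame(mid_x = gr$x[ok], mid_y = gr$y[ok],
                             angle_deg = angles[i])
  }
  placements <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(placements))
    placements <- data.frame(mid_x = numeric(0), mid_y = numeric(0),
                             angle_deg = numeric(0))
  rownames(placements) <- NULL
  structure(list(placements = placements, length_px = rs$length_px,
                 grid_step = rs$grid_step, angle_step = config$angle_step,
                 length_fraction = config$length_fraction, axes = rs$axes),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf(
    "placement_set: %d placements, filament %.3g px (%.2f x major axis), grid %.3g px / %g deg\n",
    nrow(x$placements), x$length_px, x$length_fraction, x$grid_step,
    x$angle_step))
  invisible(x)
}

#' Filament probability-density heat map
#'
#' Accumulates all valid placements on the contour's pixel grid and
#' normalizes the result to total 1 over the whole image. With the default
#' `"coverage"` density every pixel covered by a filament body receives
#' weight 1 per placement, so a pixel's value is proportional to the number
#' of filaments passing through it.
#'
#' @param contour a [shape_contour()].
#' @param config a [model_config()].
#' @return A `heat_map`: list with `values` (matrix indexed \[x, y\],
#'   summing to 1), `extent` (`c(xmin, xmax, ymin, ymax)`, 0-based pixel
#'   centres), `total` and the `placement_set` used.
#' @export
heat_map <- function(contour, config = model_config()) {
  ps <- enumerate_placements(contour, config)
  pl <- ps$placements
  if (nrow(pl) == 0)
    stop_no_placement(sprintf(
      "no valid placement for length_fraction %.3g (filament %.3g px)",
      config$length_fraction, ps$length_px))
  ras <- rasterize_contour(contour)
  dims <- dim(ras$mask)
  off <- ras$offset
  acc <- numeric(prod(dims))
  if (config$density == "midpoint") {
    ix <- round(pl$mid_x) - off[1] + 1
    iy <- round(pl$mid_y) - off[2] + 1
    idx <- (iy - 1) * dims[1] + ix
    tab <- tabulate(idx, nbins = prod(dims))
    acc <- acc + tab
  } else {
    th <- pl$angle_deg * pi / 180
    hx <- ps$length_px / 2 * cos(th); hy <- ps$length_px / 2 * sin(th)
    nsamp <- max(2L, ceiling(ps$length_px / 0.5) + 1L)
    ts <- seq(-1, 1, length.out = nsamp)
    chunk <- max(1L, floor(5e6 / nsamp))
    starts <- seq(1, nrow(pl), by = chunk)
    for (s in starts) {
      rows <- s:min(s + chunk - 1, nrow(pl))
      m <- length(rows)
      px <- rep(pl$mid_x[rows], times = nsamp) +
        rep(hx[rows], times = nsamp) * rep(ts, each = m)
      py <- rep(pl$mid_y[rows], times = nsamp) +
        rep(hy[rows], times = nsamp) * rep(ts, each = m)
      ix <- round(px) - off[1] + 1
      iy <- round(py) - off[2] + 1
      pix <- (iy - 1) * dims[1] + ix
      # one unit of weight per (placement, pixel) pair
      key <- (rep(rows, times = nsamp) - 1) * prod(dims) + pix
      pix <- pix[!duplicated(key)]
      acc <- acc + tabulate(pix, nbins = prod(dims))
    }
  }
  values <- matrix(acc, nrow = dims[1], ncol = dims[2])
  values[!ras$mask] <- 0  # clip rounding spill-over at the boundary
  total <- sum(values)
  if (total <= 0) stop_no_placement("all deposited weight fell outside the contour")
  values <- values / total
  structure(list(values = values,
                 extent = c(off[1], off[1] + dims[1] - 1,
                            off[2], off[2] + dims[2] - 1),
                 total = sum(values), placements = ps,
                 pixel_size = contour$pixel_size),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("heat_map: %d x %d px, extent [%g, %g] x [%g, %g], total %.9g\n",
              nrow(x$values), ncol(x$values), x$extent[1], x$extent[2],
              x$extent[3], x$extent[4], x$total))
  invisible(x)
}

#' Model angular distribution of confined filaments
#'
#' Folds every valid placement's orientation into \[0, 90\] degrees
#' (mirror symmetry) relative to the contour's major axis — the contour is
#' aligned internally before enumeration — and bins the placements with
#' equal weight.
#'
#' @param contour a [shape_contour()].
#' @param config a [model_config()].
#' @param n_bins number of bins over \[0, 90\].
#' @param fold set `FALSE` for the unfolded distribution over \[0, 180\].
#' @return An `angular_distribution` (see
#'   [angular_distribution_from_angles()]) with attribute `n_placements`.
#' @export
angular_distribution <- function(contour, config = model_config(),
                                 n_bins = 18, fold = TRUE) {
  aligned <- align_to_major_axis(contour)
  ps <- enumerate_placements(aligned, config)
  if (nrow(ps$placements) == 0)
    stop_no_placement(sprintf(
      "no valid placement for length_fraction %.3g", config$length_fraction))
  ang <- ps$placements$angle_deg
  if (fold) {
    dist <- angular_distribution_from_angles(fold_angle(ang), n_bins,
                                             domain = 90)
  } else {
    dist <- angular_distribution_from_angles(ang %% 180, n_bins,
                                             domain = 180)
  }
  attr(dist, "n_placements") <- nrow(ps$placements)
  dist
}

#' Sweep filament lengths
#'
#' Computes the folded angular distribution for a range of filament
#' lengths, expressed as fractions of the major axis (default 5 to 95%).
#' Fractions admitting no placement yield a flagged empty entry rather than
#' an error.
#'
#' @param contour a [shape_contour()].
#' @param config a [model_config()]; its `length_fraction` is overridden.
#' @param fractions numeric vector of length fractions in (0, 1].
#' @param n_bins number of bins over \[0, 90\].
#' @return A named list (class `length_sweep`), one entry per fraction:
#'   either an `angular_distribution` or `list(empty = TRUE, fraction = f)`.
#' @export
sweep_lengths <- function(contour, config = model_config(),
                          fractions = seq(0.05, 0.95, by = 0.05),
                          n_bins = 18) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop_invalid_input("fractions must lie in (0, 1]")
  out <- lapply(fractions, function(f) {
    cf <- config
    cf$length_fraction <- f
    tryCatch(angular_distribution(contour, cf, n_bins = n_bins),
             guv_no_placement = function(e) list(empty = TRUE, fraction = f))
  })
  names(out) <- formatC(fractions, format = "fg")
  structure(out, class = "length_sweep", fractions = fractions)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Monte-Carlo rejection sampler over filament placements
#'
#' Independent stochastic counterpart of [enumerate_placements()]: proposes
#' uniform random midpoints in the contour's bounding box and uniform
#' random orientations, and accepts a placement when
#' `containment_samples` points along the filament body all lie inside the
#' contour (point-sampled containment, deliberately a different route from
#' the exact edge-crossing tests of the grid enumeration). Proposals are
#' drawn in seeded batches until `n` placements have been accepted.
#'
#' @param contour a [shape_contour()].
#' @param config a [model_config()].
#' @param n Monte-Carlo sample size (number of accepted placements).
#' @param seed integer seed; the sampler is deterministic given the seed.
#' @param max_proposals cap on total proposals, guarding against
#'   vanishing acceptance rates.
#' @return Data frame of accepted placements (`mid_x`, `mid_y`,
#'   `angle_deg`) with attribute `n_proposals`.
#' @export
sample_placements_mc <- function(contour, config = model_config(),
                                 n = 1e5, seed = 1,
                                 max_proposals = 500 * n) {
  assert_contour(contour)
  assert_config(config)
  rs <- resolve_config(contour, config)
  pts <- contour$points
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  half <- rs$length_px / 2
  batch <- 5e5
  with_seed(seed, {
    acc <- list()
    n_acc <- 0
    proposals <- 0
    while (n_acc < n && proposals < max_proposals) {
      m <- min(batch, max_proposals - proposals)
      proposals <- proposals + m
      mx <- runif(m, xr[1], xr[2])
      my <- runif(m, yr[1], yr[2])
      th <- runif(m, 0, 180)
      rad <- th * pi / 180
      dx <- half * cos(rad); dy <- half * sin(rad)
      ok <- segments_sampled_inside_cpp(mx - dx, my - dy, mx + dx, my + dy,
                                        pts[, 1], pts[, 2],
                                        config$containment_samples)
      if (any(ok)) {
        acc[[length(acc) + 1]] <- data.frame(mid_x = mx[ok], mid_y = my[ok],
                                             angle_deg = th[ok])
        n_acc <- n_acc + sum(ok)
      }
    }
    out <- if (length(acc) > 0) do.call(rbind, acc) else
      data.frame(mid_x = numeric(0), mid_y = numeric(0),
                 angle_deg = numeric(0))
    if (nrow(out) > n) out <- out[seq_len(n), , drop = FALSE]
    if (nrow(out) < n)
      warning(sprintf("accepted only %d of %d requested placements",
                      nrow(out), n))
    attr(out, "n_proposals") <- proposals
    out
  })
}

#' Monte-Carlo angular distribution
#'
#' Folded angular distribution of the accepted placements of
#' [sample_placements_mc()], measured relative to the contour's major axis.
#' Serves as the stochastic oracle against which the deterministic grid
#' enumeration is validated (total variation distance).
#'
#' @inheritParams sample_placements_mc
#' @param n_bins number of bins over \[0, 90\].
#' @return An `angular_distribution`.
#' @export
mc_angular_distribution <- function(contour, config = model_config(),
                                    n = 1e5, seed = 1, n_bins = 18) {
  aligned <- align_to_major_axis(contour)
  acc <- sample_placements_mc(aligned, config, n = n, seed = seed)
  if (nrow(acc) == 0)
    stop_no_placement("Monte-Carlo sampler accepted no placement")
  angular_distribution_from_angles(fold_angle(acc$angle_deg), n_bins,
                                   domain = 90)
}
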