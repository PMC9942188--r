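# Planar polygon primitives: contour construction and validation,
# containment tests, equivalent-ellipse axis measurement, alignment.
#
# Conventions: coordinates are 0-based pixels, x rightward, y downward;
# angles are measured from the +x axis in degrees and reduced to [0, 180).
# Boundary points count as inside.

#' Construct a closed planar contour
#'
#' A `shape_contour` is a simple (non-self-intersecting) closed polygon in
#' pixel coordinates with an attached physical pixel size, representing a
#' GUV or micropattern outline at a fixed imaging plane. The last point is
#' implicitly connected to the first; a duplicated closing point is dropped.
#'
#' @param points two-column matrix or data frame of x, y vertex coordinates
#'   (pixels), in order around the polygon.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param label free-text label, e.g. `"stripe"` or `"crossbow"`.
#' @return An object of class `shape_contour`: a list with elements
#'   `points` (n x 2 matrix), `pixel_size` and `label`.
#' @examples
#' sq <- shape_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), pixel_size = 0.1)
#' contour_area(sq)
#' @export
shape_contour <- function(points, pixel_size = 1, label = "") {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2 || anyNA(pts) || any(!is.finite(pts)))
    stop_invalid_input("contour points must be a finite numeric n x 2 matrix")
  colnames(pts) <- c("x", "y")
  n <- nrow(pts)
  if (n >= 2 && isTRUE(all.equal(pts[1, ], pts[n, ], check.attributes = FALSE)))
    pts <- pts[-n, , drop = FALSE]
  if (nrow(pts) < 3)
    stop_invalid_input("a contour needs at least 3 distinct points")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_invalid_input("pixel_size must be a single positive number")
  if (!polygon_is_simple_cpp(pts[, 1], pts[, 2]))
    stop_invalid_input("contour polygon is not simple (self-intersects)")
  if (abs(shoelace_area(pts)) <= 0)
    stop_invalid_input("contour encloses zero area")
  structure(list(points = pts, pixel_size = pixel_size,
                 label = as.character(label)[1]),
            class = "shape_contour")
}

#' @export
print.shape_contour <- function(x, ...) {
  ax <- measure_axes(x)
  cat(sprintf(
    "shape_contour '%s': %d vertices, pixel size %g um/px\n  major %.3g um, minor %.3g um, ratio %.3g, angle %.3g deg\n",
    x$label, nrow(x$points), x$pixel_size,
    ax$major_length, ax$minor_length, ax$ratio, ax$major_angle))
  invisible(x)
}

is_shape_contour <- function(x) inherits(x, "shape_contour")

assert_contour <- function(contour) {
  if (!is_shape_contour(contour))
    stop_invalid_input("expected a 'shape_contour' object")
  invisible(contour)
}

# signed area (shoelace); positive when vertices run counterclockwise in
# the stored coordinate system
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Enclosed area of a contour
#'
#' @param contour a [shape_contour()].
#' @param units `"px"` for square pixels or `"um"` for square micrometres.
#' @return Enclosed area (non-negative scalar).
#' @export
contour_area <- function(contour, units = c("px", "um")) {
  assert_contour(contour)
  units <- match.arg(units)
  a <- abs(shoelace_area(contour$points))
  if (units == "um") a * contour$pixel_size^2 else a
}

contour_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Test whether points lie inside a contour
#'
#' Boundary points count as inside: a filament touching the rigid boundary
#' is still confined by it.
#'
#' @param contour a [shape_contour()].
#' @param p numeric vector `c(x, y)` or an n x 2 matrix of points (pixels).
#' @return Logical vector, one element per point.
#' @examples
#' sq <- shape_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' contains_point(sq, c(0.5, 0.5))
#' contains_point(sq, rbind(c(2, 2), c(0, 0.5)))
#' @export
contains_point <- function(contour, p) {
  assert_contour(contour)
  p <- to_point_matrix(p)
  points_in_polygon_cpp(p[, 1], p[, 2],
                        contour$points[, 1], contour$points[, 2])
}

to_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2) stop_invalid_input("a point must have 2 coordinates")
    p <- matrix(p, ncol = 2)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2 || !is.numeric(p) || any(!is.finite(p)))
    stop_invalid_input("points must be finite numeric x,y pairs")
  p
}

#' Test whether straight segments lie entirely inside a contour
#'
#' True when both endpoints are inside (boundary included) and the segment
#' does not cross any polygon edge; touching the boundary without crossing
#' is allowed. This is the rigid-boundary condition a straight filament
#' must satisfy to fit within the confinement.
#'
#' @param contour a [shape_contour()].
#' @param p1,p2 endpoints: numeric `c(x, y)` vectors or n x 2 matrices of
#'   matched rows.
#' @return Logical vector, one element per segment.
#' @examples
#' sq <- shape_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' segment_inside(sq, c(0.2, 0.5), c(0.8, 0.5))
#' segment_inside(sq, c(0.5, 0.5), c(1.5, 0.5))
#' @export
segment_inside <- function(contour, p1, p2) {
  assert_contour(contour)
  p1 <- to_point_matrix(p1); p2 <- to_point_matrix(p2)
  if (nrow(p1) != nrow(p2))
    stop_invalid_input("p1 and p2 must have the same number of points")
  segments_inside_cpp(p1[, 1], p1[, 2], p2[, 1], p2[, 2],
                      contour$points[, 1], contour$points[, 2])
}

# exact second central moments of the filled polygon (Green's theorem)
polygon_moments <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  exx <- sum((x^2 + x * x2 + x2^2) * cr) / (12 * a) - cx^2
  eyy <- sum((y^2 + y * y2 + y2^2) * cr) / (12 * a) - cy^2
  exy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / (24 * a) -
    cx * cy
  list(area = abs(a), centroid = c(cx, cy),
       cov = matrix(c(exx, exy, exy, eyy), 2, 2))
}

#' Measure major and minor axes of a contour
#'
#' The default method fits the ellipse with the same normalized second
#' central moments as the filled polygon (the usual image-analysis
#' "fit ellipse"); axis lengths are the full ellipse axes. The `"feret"`
#' alternative reports the maximum caliper diameter and the minimal width
#' over the convex hull.
#'
#' @param contour a [shape_contour()].
#' @param method `"moment"` (equivalent ellipse, default) or `"feret"`.
#' @return An `axis_measurement`: list with `major_length` and
#'   `minor_length` (micrometres), `major_angle` (degrees in \[0, 180) from
#'   +x) and `ratio` (= major/minor, >= 1).
#' @examples
#' ell <- shape_contour(ellipse_points(100, 50), pixel_size = 0.1)
#' measure_axes(ell)
#' @export
measure_axes <- function(contour, method = c("moment", "feret")) {
  assert_contour(contour)
  method <- match.arg(method)
  if (method == "moment") {
    m <- polygon_moments(contour$points)
    if (m$area <= 0) stop_invalid_input("contour encloses zero area")
    e <- eigen(m$cov, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    major <- 4 * sqrt(lam[1]); minor <- 4 * sqrt(lam[2])
    ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  } else {
    h <- contour$points[grDevices::chull(contour$points), , drop = FALSE]
    d <- as.matrix(stats::dist(h))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    major <- max(d)
    v <- h[ij[2], ] - h[ij[1], ]
    ang <- atan2(v[2], v[1]) * 180 / pi
    # minimal caliper width: smallest extent over hull-edge normals
    nh <- nrow(h)
    edges <- h[c(2:nh, 1), , drop = FALSE] - h
    len <- sqrt(rowSums(edges^2))
    nrm <- cbind(-edges[, 2], edges[, 1]) / len
    widths <- vapply(seq_len(nh), function(i) {
      pr <- h %*% nrm[i, ]
      max(pr) - min(pr)
    }, numeric(1))
    minor <- min(widths)
  }
  if (minor <= 0) stop_invalid_input("degenerate contour: zero minor axis")
  ang <- ang %% 180
  structure(list(major_length = major * contour$pixel_size,
                 minor_length = minor * contour$pixel_size,
                 major_angle = ang,
                 ratio = major / minor),
            class = "axis_measurement")
}

#' @export
print.axis_measurement <- function(x, ...) {
  cat(sprintf("axes: major %.4g um, minor %.4g um, ratio %.4g, angle %.4g deg\n",
              x$major_length, x$minor_length, x$ratio, x$major_angle))
  invisible(x)
}

#' Rotate a contour so its major axis is horizontal
#'
#' Rigid rotation about the centroid bringing `major_angle` to 0; area and
#' axis lengths are preserved. Used as the reference frame for angle
#' statistics, which are measured relative to the major axis.
#'
#' @param contour a [shape_contour()].
#' @return The rotated `shape_contour`.
#' @export
align_to_major_axis <- function(contour) {
  assert_contour(contour)
  ax <- measure_axes(contour)
  rotate_contour(contour, -ax$major_angle)
}

#' Rotate a contour about its centroid
#'
#' @param contour a [shape_contour()].
#' @param angle rotation angle in degrees (counterclockwise in the stored
#'   coordinate system).
#' @return The rotated `shape_contour`.
#' @export
rotate_contour <- function(contour, angle) {
  assert_contour(contour)
  ctr <- contour_centroid(contour$points)
  th <- angle * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- sweep(contour$points, 2, ctr) %*% t(rot)
  pts <- sweep(pts, 2, ctr, "+")
  shape_contour(pts, contour$pixel_size, contour$label)
}

#' Vertices of an origin-centred ellipse
#'
#' Convenience generator for tests and examples.
#'
#' @param a,b semi-axes in pixels (a along x).
#' @param n number of vertices.
#' @param angle rotation in degrees.
#' @param center length-2 centre.
#' @return n x 2 matrix of vertex coordinates.
#' @export
ellipse_points <- function(a, b, n = 180, angle = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- angle * pi / 180
  x <- a * cos(t); y <- b * sin(t)
  cbind(center[1] + x * cos(th) - y * sin(th),
        center[2] + x * sin(th) + y * cos(th))
}

# fill a contour on an integer pixel grid; returns list(mask [x, y],
# offset = 0-based pixel coordinate of mask[1, 1])
rasterize_contour <- function(contour, pad = 1L) {
  assert_contour(contour)
  pts <- contour$points
  x0 <- floor(min(pts[, 1])) - pad; x1 <- ceiling(max(pts[, 1])) + pad
  y0 <- floor(min(pts[, 2])) - pad; y1 <- ceiling(max(pts[, 2])) + pad
  gx <- seq(x0, x1); gy <- seq(y0, y1)
  gr <- expand.grid(x = gx, y = gy)
  inside <- points_in_polygon_cpp(gr$x, gr$y, pts[, 1], pts[, 2])
  list(mask = matrix(inside, nrow = length(gx), ncol = length(gy)),
       offset = c(x0, y0))
}
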