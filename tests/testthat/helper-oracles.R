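# Independent oracles and small fixtures used across the suite. These stay
# deliberately separate from the package's own code paths.

# winding-number point-in-polygon (angle-summation form), pure R
winding_inside <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  vapply(seq_along(px), function(k) {
    dx <- vx - px[k]; dy <- vy - py[k]
    r <- sqrt(dx^2 + dy^2)
    if (any(r < eps)) return(TRUE)  # on a vertex
    dx2 <- c(dx[-1], dx[1]); dy2 <- c(dy[-1], dy[1])
    cross <- dx * dy2 - dy * dx2
    dot <- dx * dx2 + dy * dy2
    ang <- atan2(cross, dot)
    # on an edge: collinear and between the endpoints
    if (any(abs(cross) < eps * pmax(1, r * c(r[-1], r[1])) & dot < eps))
      return(TRUE)
    abs(sum(ang)) > pi  # winding number != 0
  }, logical(1))
}

# segment containment by dense point sampling against the winding oracle
sampled_segment_inside <- function(contour, p1, p2, n = 200) {
  t <- seq(0, 1, length.out = n)
  px <- p1[1] + t * (p2[1] - p1[1])
  py <- p1[2] + t * (p2[2] - p1[2])
  all(winding_inside(px, py, contour$points[, 1], contour$points[, 2]))
}

# mean distance from points to a closed polygon boundary
mean_boundary_distance <- function(pts, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  mean(vapply(seq_len(nrow(pts)), function(k) {
    px <- pts[k, 1]; py <- pts[k, 2]
    ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
    len2 <- ex^2 + ey^2
    t <- pmin(pmax(((px - a[, 1]) * ex + (py - a[, 2]) * ey) / len2, 0), 1)
    min(sqrt((a[, 1] + t * ex - px)^2 + (a[, 2] + t * ey - py)^2))
  }, numeric(1)))
}

hausdorff_distance <- function(p1, p2) {
  max(mean_max_dist(p1, p2), mean_max_dist(p2, p1))
}

mean_max_dist <- function(p1, p2) {
  max(vapply(seq_len(nrow(p1)), function(k) {
    min(sqrt((p2[, 1] - p1[k, 1])^2 + (p2[, 2] - p1[k, 2])^2))
  }, numeric(1)))
}

unit_square <- function() shape_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

l_polygon <- function() {
  shape_contour(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2)))
}

stripe_guv_contour <- function(diameter = 15, seed = 1) {
  synth_guv_contour(synth_guv_spec(pattern_spec("stripe"),
                                   guv_diameter = diameter, seed = seed))
}
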