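test_that("contour construction enforces validity", {
  expect_error(shape_contour(cbind(0:1, 0:1)), class = "guv_invalid_input")
  expect_error(shape_contour(cbind(c(0, 1, 1), c(0, 0, 0))),
               class = "guv_invalid_input")  # zero area
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(shape_contour(bowtie), class = "guv_invalid_input")
  expect_error(shape_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                             pixel_size = -1),
               class = "guv_invalid_input")
  # duplicated closing point is dropped
  closed <- shape_contour(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  expect_equal(nrow(closed$points), 4)
})

test_that("point containment handles interior, exterior and boundary", {
  sq <- unit_square()
  expect_true(contains_point(sq, c(0.5, 0.5)))
  expect_false(contains_point(sq, c(2, 2)))
  expect_true(contains_point(sq, c(0, 0.5)))   # boundary counts as inside
  expect_true(contains_point(sq, c(1, 1)))     # vertex
})

test_that("point containment agrees with a winding-number oracle", {
  set.seed(42)
  shapes <- list(unit_square(), l_polygon(),
                 shape_contour(ellipse_points(3, 1.5, n = 40)))
  for (ct in shapes) {
    r <- apply(ct$points, 2, range)
    px <- runif(1000, r[1, 1] - 0.5, r[2, 1] + 0.5)
    py <- runif(1000, r[1, 2] - 0.5, r[2, 2] + 0.5)
    got <- contains_point(ct, cbind(px, py))
    want <- winding_inside(px, py, ct$points[, 1], ct$points[, 2])
    expect_identical(got, want)
  }
})

test_that("segment containment matches the rigid-boundary condition", {
  sq <- unit_square()
  expect_true(segment_inside(sq, c(0.2, 0.5), c(0.8, 0.5)))
  expect_false(segment_inside(sq, c(0.5, 0.5), c(1.5, 0.5)))
  # chord along the boundary: touching without crossing is allowed
  expect_true(segment_inside(sq, c(0, 0), c(1, 0)))
  L <- l_polygon()
  # grazes the reflex corner tangentially: never leaves the L
  expect_true(segment_inside(L, c(0.5, 1.5), c(1.5, 0.5)))
  # genuinely cuts through the missing quadrant
  expect_false(segment_inside(L, c(0.5, 1.8), c(1.8, 0.5)))
  expect_false(sampled_segment_inside(L, c(0.5, 1.8), c(1.8, 0.5)))
})

test_that("segment containment reduces to point containment at zero length", {
  set.seed(7)
  for (ct in list(unit_square(), l_polygon())) {
    p <- cbind(runif(200, -0.5, 2.5), runif(200, -0.5, 2.5))
    expect_identical(segment_inside(ct, p, p), contains_point(ct, p))
  }
})

test_that("segment containment agrees with dense-sampling oracle on the L", {
  set.seed(11)
  L <- l_polygon()
  p1 <- cbind(runif(150, 0, 2), runif(150, 0, 2))
  p2 <- cbind(runif(150, 0, 2), runif(150, 0, 2))
  got <- segment_inside(L, p1, p2)
  # sampling must be dense: excursions through the notch can cover well
  # under 1% of a segment's length
  want <- vapply(seq_len(nrow(p1)), function(k)
    sampled_segment_inside(L, p1[k, ], p2[k, ], n = 5000), logical(1))
  expect_equal(got, want)
})

test_that("moment axes recover known shapes", {
  circ <- shape_contour(ellipse_points(50, 50, n = 180), pixel_size = 0.1)
  ax <- measure_axes(circ)
  expect_equal(ax$major_length, 10, tolerance = 0.02)
  expect_equal(ax$ratio, 1, tolerance = 0.02)

  ell <- shape_contour(ellipse_points(100, 50, n = 180), pixel_size = 0.1)
  ax <- measure_axes(ell)
  expect_equal(ax$ratio, 2, tolerance = 0.02)
  expect_equal(ax$major_length, 20, tolerance = 0.02)
  expect_equal(ax$major_angle, 0, tolerance = 0.5)

  sq <- shape_contour(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  expect_equal(measure_axes(sq)$ratio, 1, tolerance = 1e-9)
})

test_that("feret axes give caliper extents", {
  ell <- shape_contour(ellipse_points(100, 50, n = 360), pixel_size = 0.1)
  ax <- measure_axes(ell, method = "feret")
  expect_equal(ax$major_length, 20, tolerance = 0.01)
  expect_equal(ax$minor_length, 10, tolerance = 0.01)
})

test_that("axis measurement is rotation-invariant and ratio >= 1", {
  ell <- shape_contour(ellipse_points(80, 30, n = 120))
  base <- measure_axes(ell)
  for (ang in c(17, 45, 90, 133)) {
    ax <- measure_axes(rotate_contour(ell, ang))
    expect_gte(ax$ratio, 1)
    expect_equal(ax$major_length, base$major_length, tolerance = 0.01)
    expect_equal(ax$minor_length, base$minor_length, tolerance = 0.01)
    expect_equal(ax$major_angle, ang %% 180, tolerance = 0.5)
  }
})

test_that("alignment zeroes the major angle and preserves area", {
  ell <- shape_contour(ellipse_points(60, 25, n = 90, angle = 30))
  al <- align_to_major_axis(ell)
  expect_equal(measure_axes(al)$major_angle %% 180, 0, tolerance = 1e-6)
  expect_equal(contour_area(al), contour_area(ell), tolerance = 1e-9)
  # aligning twice is a no-op
  al2 <- align_to_major_axis(al)
  expect_equal(al2$points, al$points, tolerance = 1e-6)
})
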