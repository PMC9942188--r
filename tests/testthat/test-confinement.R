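# The model's contract: exact enumeration of placements on a grid,
# normalized heat maps, folded angular distributions, length sweeps.

small_circle <- function(r = 30) shape_contour(ellipse_points(r, r, n = 90))

test_that("model configuration is validated", {
  expect_error(model_config(0), class = "guv_invalid_input")
  expect_error(model_config(1.2), class = "guv_invalid_input")
  expect_error(model_config(0.5, angle_step = 7), class = "guv_invalid_input")
  expect_error(model_config(0.5, grid_step = -1), class = "guv_invalid_input")
  expect_s3_class(model_config(0.5, angle_step = 4), "model_config")
})

test_that("placements that cannot fit give an empty set, central chords fit", {
  circ <- small_circle(10)
  # a filament of one radius always fits near the centre, at every angle
  ps <- enumerate_placements(circ, model_config(0.5, grid_step = 2,
                                                angle_step = 30))
  expect_gt(nrow(ps$placements), 0)
  mids <- ps$placements[ps$placements$mid_x^2 + ps$placements$mid_y^2 < 1, ]
  expect_setequal(unique(mids$angle_deg), c(15, 45, 75, 105, 135, 165))
  # rectangle 5 x 15 with a 10-long filament: perpendicular never fits
  rect <- shape_contour(cbind(c(0, 150, 150, 0), c(0, 0, 50, 50)))
  frac <- 100 / (measure_axes(rect)$major_length)
  ps <- enumerate_placements(rect, model_config(frac, grid_step = 5,
                                                angle_step = 90))
  # cell-centred angles 45 and 135: sin(45) * 100 = 71 > 50, nothing fits
  expect_equal(nrow(ps$placements), 0)
})

test_that("enumeration is deterministic and matches brute-force on the grid", {
  rect <- shape_contour(cbind(c(0, 30, 30, 0), c(0, 0, 10, 10)))
  cfg <- model_config(28 / measure_axes(rect)$major_length, grid_step = 2,
                      angle_step = 30)
  ps1 <- enumerate_placements(rect, cfg)
  ps2 <- enumerate_placements(rect, cfg)
  expect_identical(ps1$placements, ps2$placements)
  # brute force: dense-sampled containment via the winding oracle
  gx <- seq(0, 30, by = 2); gy <- seq(0, 10, by = 2)
  angles <- c(15, 45, 75, 105, 135, 165)
  half <- ps1$length_px / 2
  want <- 0
  for (x in gx) for (y in gy) {
    if (!winding_inside(x, y, rect$points[, 1], rect$points[, 2])) next
    for (a in angles) {
      th <- a * pi / 180
      p1 <- c(x - half * cos(th), y - half * sin(th))
      p2 <- c(x + half * cos(th), y + half * sin(th))
      if (sampled_segment_inside(rect, p1, p2, n = 400)) want <- want + 1
    }
  }
  expect_equal(nrow(ps1$placements), want)
})

test_that("heat maps are normalized, non-negative and zero outside", {
  ct <- stripe_guv_contour()
  hm <- heat_map(ct, model_config(0.9))
  expect_equal(hm$total, 1, tolerance = 1e-9)
  expect_true(all(hm$values >= 0))
  ras <- guvconfine:::rasterize_contour(ct)
  expect_true(all(hm$values[!ras$mask] == 0))
  # midpoint-density variant obeys the same contract
  hm2 <- heat_map(ct, model_config(0.9, density = "midpoint"))
  expect_equal(hm2$total, 1, tolerance = 1e-9)
  # too-long filament raises the dedicated condition
  tiny <- small_circle(8)
  expect_error(
    suppressWarnings(heat_map(tiny, model_config(1, grid_step = 6,
                                                 angle_step = 90))),
    class = "guv_no_placement")
})

test_that("heat map matches an independent per-triple brute force", {
  rect <- shape_contour(cbind(c(0, 30, 30, 0), c(0, 0, 10, 10)))
  cfg <- model_config(28 / measure_axes(rect)$major_length, grid_step = 2,
                      angle_step = 30)
  hm <- heat_map(rect, cfg)
  ps <- enumerate_placements(rect, cfg)
  # independent accumulation: per placement, walk the filament at 0.5 px
  # and mark covered pixels in a plain R loop
  dims <- dim(hm$values)
  off <- c(hm$extent[1], hm$extent[3])
  acc <- matrix(0, dims[1], dims[2])
  nsamp <- max(2L, ceiling(ps$length_px / 0.5) + 1L)
  for (k in seq_len(nrow(ps$placements))) {
    th <- ps$placements$angle_deg[k] * pi / 180
    t <- seq(-0.5, 0.5, length.out = nsamp)
    xs <- round(ps$placements$mid_x[k] + t * ps$length_px * cos(th))
    ys <- round(ps$placements$mid_y[k] + t * ps$length_px * sin(th))
    for (pix in unique(paste(xs, ys))) {
      xy <- as.numeric(strsplit(pix, " ")[[1]])
      i <- xy[1] - off[1] + 1; j <- xy[2] - off[2] + 1
      acc[i, j] <- acc[i, j] + 1
    }
  }
  mask <- guvconfine:::rasterize_contour(rect)$mask
  acc[!mask] <- 0
  expect_equal(hm$values, acc / sum(acc), tolerance = 1e-12)
})

test_that("circle distributions are uniform and heat maps 4-fold symmetric", {
  circ <- small_circle(30)
  d <- angular_distribution(circ, model_config(0.5, grid_step = 1.5))
  expect_lt(max(abs(d$probabilities * 18 - 1)), 0.05)
  hm <- heat_map(circ, model_config(0.5, grid_step = 3, angle_step = 5))
  v <- hm$values
  rot <- t(v[rev(seq_len(nrow(v))), ])  # 90 degree rotation of the grid
  expect_equal(dim(rot), dim(v))
  expect_lt(max(abs(rot - v)), max(v) * 0.1)
})

test_that("rectangle angular support respects the arcsin(w/L) bound", {
  rect <- shape_contour(cbind(c(0, 150, 150, 0), c(0, 0, 50, 50)))
  frac <- 100 / measure_axes(rect)$major_length
  ps <- enumerate_placements(align_to_major_axis(rect), model_config(frac))
  folded <- fold_angle(ps$placements$angle_deg)
  expect_lte(max(folded), asin(50 / 100) * 180 / pi)
})

test_that("unfolded distributions are symmetric about 90 for mirror shapes", {
  ct <- stripe_guv_contour()
  d <- angular_distribution(ct, model_config(0.7, grid_step = 3), n_bins = 36,
                            fold = FALSE)
  p <- d$probabilities
  expect_lt(sum(abs(p - rev(p))) / 2, 0.02)
})

test_that("length sweeps concentrate stripe mass into low angles", {
  ct <- stripe_guv_contour()
  sw <- sweep_lengths(ct, model_config(grid_step = 3),
                      fractions = c(0.05, 0.5, 0.9))
  expect_named(sw, c("0.05", "0.5", "0.9"))
  low <- vapply(sw, function(d) d$probabilities[1], numeric(1))
  expect_true(all(diff(low) > 0))  # non-decreasing with filament length
  # impossible fraction flagged, not an error
  tiny <- small_circle(8)
  sw2 <- suppressWarnings(
    sweep_lengths(tiny, model_config(grid_step = 4, angle_step = 45),
                  fractions = c(0.5, 1)))
  expect_s3_class(sw2[["0.5"]], "angular_distribution")
  expect_error(sweep_lengths(ct, model_config(), fractions = c(0, 0.5)),
               class = "guv_invalid_input")
})

test_that("short filaments approach a uniform orientation distribution", {
  ct <- stripe_guv_contour()
  d <- angular_distribution(ct, model_config(0.05, grid_step = 3))
  expect_lt(tv_distance(d, uniform_angular_distribution()), 0.05)
})

test_that("the Monte-Carlo sampler reproduces grid distributions", {
  circ <- small_circle(25)
  cfg <- model_config(0.6, grid_step = 2)
  dg <- angular_distribution(circ, cfg)
  dm <- mc_angular_distribution(circ, cfg, n = 2e4, seed = 5)
  expect_lt(tv_distance(dg, dm), 0.02)
  # determinism under the seed
  a1 <- sample_placements_mc(circ, cfg, n = 500, seed = 9)
  a2 <- sample_placements_mc(circ, cfg, n = 500, seed = 9)
  expect_identical(a1, a2)
})
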