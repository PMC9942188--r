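test_that("pattern masks have the specified physical geometry", {
  st <- make_pattern_mask(pattern_spec("stripe", size = 15, stripe_width = 5,
                                       pixel_size = 0.1))
  on <- which(st$mask, arr.ind = TRUE)
  expect_equal(diff(range(on[, 1])) + 1, 150)
  expect_equal(diff(range(on[, 2])) + 1, 50)

  circ <- make_pattern_mask(pattern_spec("circle", size = 10))
  expect_equal(sum(circ$mask), pi * 50^2, tolerance = 0.02)

  # cross is pixel-exact the union of two perpendicular stripes
  cr <- make_pattern_mask(pattern_spec("cross", size = 15))
  ctr <- cr$center
  d <- dim(cr$mask)
  px <- rep(seq_len(d[1]) - 1, times = d[2]) - ctr[1]
  py <- rep(seq_len(d[2]) - 1, each = d[1]) - ctr[2]
  horiz <- px >= -75 & px < 75 & py >= -25 & py < 25
  vert <- py >= -75 & py < 75 & px >= -25 & px < 25
  expect_identical(as.vector(cr$mask), horiz | vert)

  expect_error(pattern_spec("stripe", size = 15, stripe_width = 0.5),
               class = "guv_invalid_input")
  expect_error(pattern_spec("circle", size = 0.5),
               class = "guv_invalid_input")
})

test_that("crossbow mask is an open arc plus bar inside its silhouette", {
  cb <- make_pattern_mask(pattern_spec("crossbow", size = 15))
  expect_s3_class(cb$contour, "shape_contour")
  # the mask is a thin adhesive outline: much smaller than the silhouette
  expect_lt(sum(cb$mask), contour_area(cb$contour))
  # every mask pixel lies inside (or on) the silhouette
  on <- which(cb$mask, arr.ind = TRUE) - 1
  expect_true(all(contains_point(cb$contour, on)))
})

test_that("deformation of generated contours peaks at intermediate sizes", {
  diams <- c(5, 7.5, 10, 12.5, 15, 20, 25, 30, 35)
  ratios <- vapply(diams, function(d)
    measure_axes(stripe_guv_contour(d))$ratio, numeric(1))
  expect_lt(ratios[1], 1.05)
  expect_lt(ratios[length(ratios)], 1.05)
  peak <- which.max(ratios)
  expect_true(diams[peak] > 5 && diams[peak] < 35)
  expect_true(all(diff(ratios[1:peak]) > 0))
  expect_true(all(diff(ratios[peak:length(ratios)]) < 0))
  # compact patterns stay near-circular
  for (k in c("cross", "crossbow", "circle")) {
    ct <- synth_guv_contour(synth_guv_spec(pattern_spec(k),
                                           guv_diameter = 15))
    expect_lt(measure_axes(ct)$ratio, 1.1)
  }
})

test_that("synthetic images are seeded, recoverable and ground-truthed", {
  spec <- synth_guv_spec(pattern_spec("stripe"), guv_diameter = 12,
                         noise_sigma = 0.1, seed = 5)
  im1 <- synth_image(spec)
  im2 <- synth_image(spec)
  expect_identical(im1$channels$membrane, im2$channels$membrane)
  spec2 <- synth_guv_spec(pattern_spec("stripe"), guv_diameter = 12,
                          noise_sigma = 0.1, seed = 6)
  expect_false(identical(synth_image(spec2)$channels$membrane,
                         im1$channels$membrane))
  # noiseless round trip within 2 px mean boundary error
  spec0 <- synth_guv_spec(pattern_spec("stripe"), guv_diameter = 12,
                          noise_sigma = 0, seed = 5)
  im0 <- synth_image(spec0)
  ct <- extract_contour(im0$channels$membrane, pixel_size = im0$pixel_size)
  expect_lt(mean_boundary_distance(ct$points, im0$contour$points), 2)
  # noisy recovery within 5% on the axis ratio
  ctn <- extract_contour(im1$channels$membrane, pixel_size = im1$pixel_size)
  expect_equal(measure_axes(ctn)$ratio, measure_axes(im1$contour)$ratio,
               tolerance = 0.05)
})

test_that("synthetic z-stacks peak at the bottom and narrow upward", {
  zs <- synth_zstack(synth_guv_spec(pattern_spec("stripe"), guv_diameter = 15,
                                    seed = 3))
  pl <- select_analysis_plane(zs$stack)
  expect_equal(pl$surface_index, 1)
  areas <- vapply(zs$contours, contour_area, numeric(1))
  w <- which.max(areas)
  expect_true(all(diff(areas[w:length(areas)]) < 0))
  r <- vapply(zs$contours, function(ct) measure_axes(ct)$ratio, numeric(1))
  expect_gt(r[1], r[length(r)])
  expect_error(synth_zstack(synth_guv_spec(pattern_spec("stripe"),
                                           guv_diameter = 15), n_slices = 2),
               class = "guv_invalid_input")
})

test_that("synthetic filaments carry exact ground truth at zero jitter", {
  ct <- stripe_guv_contour()
  ref <- measure_axes(ct)$major_angle
  sp <- synth_filament_spec(ct, length_fraction = 0.8, n_filaments = 40,
                            jitter_sigma = 0, points_per_filament = 8,
                            seed = 17)
  fil <- synth_filaments(sp, config = model_config(0.8, grid_step = 3))
  got <- vapply(fil$traces, function(tr)
    filament_angle(tr, reference_angle = ref)$angle, numeric(1))
  expect_equal(got, fil$true_angles, tolerance = 1e-6)
})

test_that("jittered filaments recover angles within a few degrees", {
  ct <- stripe_guv_contour()
  ref <- measure_axes(ct)$major_angle
  sp <- synth_filament_spec(ct, length_fraction = 0.5, n_filaments = 60,
                            jitter_sigma = 0.5, points_per_filament = 10,
                            seed = 23)
  fil <- synth_filaments(sp, config = model_config(0.5, grid_step = 3))
  got <- vapply(fil$traces, function(tr)
    filament_angle(tr, reference_angle = ref)$angle, numeric(1))
  # filaments here are ~77 px long; 0.5 px jitter barely moves the axis
  expect_lt(max(abs(got - fil$true_angles)), 3)
})

test_that("filament generation round-trips through the snake dialect", {
  ct <- stripe_guv_contour()
  sp <- synth_filament_spec(ct, length_fraction = 0.7, n_filaments = 10,
                            seed = 29)
  f <- tempfile(fileext = ".txt")
  fil <- synth_filaments(sp, config = model_config(0.7, grid_step = 4),
                         path = f)
  back <- parse_snake_file(f)
  expect_length(back, 10)
  for (i in seq_along(back))
    expect_equal(back[[i]]$points, fil$traces[[i]]$points, tolerance = 1e-6)
  # determinism under the spec seed
  fil2 <- synth_filaments(sp, config = model_config(0.7, grid_step = 4))
  expect_identical(fil$placements, fil2$placements)
})
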