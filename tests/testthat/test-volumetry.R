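# Contour-based volumetry on synthetic images with known geometry.

test_that("spheroid closed form handles ellipsoids, spheres and errors", {
  expect_equal(spheroid_volume(6, 4), 16 * pi, tolerance = 1e-12)
  r <- 1.7
  expect_equal(spheroid_volume(2 * r, 2 * r), (4 / 3) * pi * r^3,
               tolerance = 1e-12)
  expect_error(spheroid_volume(4, 6), "long axis")
  expect_error(spheroid_volume(4, 0), "positive")
})

test_that("binarisation keeps the largest filled component", {
  img <- generate_cell_image(La = 8, Lb = 6, pixel_size = 0.1,
                             dim = c(200L, 160L))
  mask <- binarize(img)
  drawn_area <- pi * (8 / 2) * (6 / 2)
  expect_equal(sum(mask) * 0.1^2, drawn_area, tolerance = 0.02)

  # a second, smaller blob is discarded
  img2 <- img
  img2$pixels[5:10, 5:10] <- 0.9
  mask2 <- binarize(img2)
  expect_equal(sum(mask2), sum(mask), tolerance = 0.01)

  # uniform background: nothing to segment
  blank <- img
  blank$pixels[] <- 0.2
  expect_error(binarize(blank), "no cell detected")
})

test_that("contour extraction recovers axes of drawn ellipses", {
  img <- generate_cell_image(La = 6, Lb = 4, pixel_size = 0.05,
                             dim = c(300L, 260L))
  ct <- extract_contour(binarize(img), img$pixel_size)
  expect_equal(ct$long_axis, 6, tolerance = 0.1 / 6)
  expect_equal(ct$short_axis, 4, tolerance = 0.1 / 4)

  # circle: both axes equal the diameter
  circ <- generate_cell_image(La = 5, Lb = 5, pixel_size = 0.05,
                              dim = c(260L, 260L))
  cc <- extract_contour(binarize(circ), circ$pixel_size)
  expect_equal(cc$long_axis, 5, tolerance = 0.03)
  expect_equal(cc$short_axis, 5, tolerance = 0.03)

  # rotation leaves the axes unchanged
  rot <- generate_cell_image(La = 6, Lb = 4, orientation = 0.9,
                             pixel_size = 0.05, dim = c(300L, 260L))
  cr <- extract_contour(binarize(rot), rot$pixel_size)
  expect_equal(cr$long_axis, ct$long_axis, tolerance = 0.02)
  expect_equal(cr$short_axis, ct$short_axis, tolerance = 0.02)
})

test_that("disk integration matches closed forms", {
  # rectangle profile = cylinder, exact under the trapezoidal rule
  prof <- data.frame(position = seq(0, 2, by = 0.01),
                     half_width = rep(0.5, 201))
  contour <- structure(list(mask = matrix(1, 1, 1), area = 1,
                            long_axis = 2, short_axis = 1, orientation = 0,
                            axis_profile = prof),
                       class = "contour_result")
  expect_equal(volume_of_revolution(contour), pi * 0.5^2 * 2,
               tolerance = 1e-12)

  # drawn ellipse: prolate spheroid within 3%
  img <- generate_cell_image(La = 6, Lb = 4, pixel_size = 0.05,
                             dim = c(300L, 260L))
  v <- volume_of_revolution(extract_contour(binarize(img), 0.05))
  expect_equal(v, 16 * pi, tolerance = 0.03)

  # sphere within 3%
  circ <- generate_cell_image(La = 5, Lb = 5, pixel_size = 0.05,
                              dim = c(260L, 260L))
  vc <- volume_of_revolution(extract_contour(binarize(circ), 0.05))
  expect_equal(vc, (4 / 3) * pi * 2.5^3, tolerance = 0.03)

  empty <- contour
  empty$axis_profile$half_width <- 0
  expect_error(volume_of_revolution(empty), "degenerate")
})

test_that("estimated volume converges and is invariant to pose and scale", {
  # resolution: >= 200 px along the long axis brings the error under 1%
  img_hi <- generate_cell_image(La = 10, Lb = 7, pixel_size = 0.04,
                                dim = c(400L, 320L))
  v_hi <- measure_cell_volume(img_hi)$volume_um3
  expect_equal(v_hi, spheroid_volume(10, 7), tolerance = 0.01)

  # orientation sweep: volume varies by less than 3%
  vols <- sapply(seq(0, pi * 0.9, length.out = 5), function(th) {
    im <- generate_cell_image(La = 10, Lb = 7, orientation = th,
                              pixel_size = 0.1, dim = c(200L, 180L))
    measure_cell_volume(im)$volume_um3
  })
  expect_lt((max(vols) - min(vols)) / mean(vols), 0.03)

  # scaling the cell by s scales the volume by s^3
  base <- measure_cell_volume(
    generate_cell_image(La = 8, Lb = 5, pixel_size = 0.1,
                        dim = c(260L, 220L)))$volume_um3
  for (s in c(0.5, 2)) {
    vs <- measure_cell_volume(
      generate_cell_image(La = 8 * s, Lb = 5 * s, pixel_size = 0.1 * s,
                          dim = c(260L, 220L)))$volume_um3
    expect_equal(vs / base, s^3, tolerance = 0.02)
  }
})

test_that("noisy images still yield volumes within 5% of truth", {
  img <- generate_cell_image(La = 10, Lb = 7, orientation = 0.4,
                             pixel_size = 0.1, noise_sd = 0.06, seed = 3,
                             dim = c(200L, 180L))
  v <- measure_cell_volume(img)$volume_um3
  expect_equal(v, img$ground_truth$true_volume, tolerance = 0.05)
})

test_that("images round-trip through PNG files", {
  img <- generate_cell_image(La = 8, Lb = 6, pixel_size = 0.1,
                             dim = c(120L, 100L))
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(img$pixels), path)
  back <- read_cell_image(path, pixel_size = 0.1)
  v1 <- measure_cell_volume(img)$volume_um3
  v2 <- measure_cell_volume(back)$volume_um3
  expect_equal(v2, v1, tolerance = 0.01)
})
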