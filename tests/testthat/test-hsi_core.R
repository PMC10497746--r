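test_that("calibration implements (raw - dark) / (white - dark)", {
  d <- c(3L, 4L, 2L)
  white <- array(1, d); dark <- array(0, d)
  cal <- calibration_set(white, white, dark, c(500, 600))
  expect_equal(calibrate_cube(cal)$data, array(1, d))        # raw = white
  cal$raw <- dark
  expect_equal(calibrate_cube(cal)$data, array(0, d))        # raw = dark

  raw <- array(0.6, d); w2 <- array(1, d); dk <- array(0.2, d)
  out <- calibrate_cube(calibration_set(raw, w2, dk, c(500, 600)))
  expect_equal(out$data[1, 1, 1], 0.5)
  expect_equal(out$wavelengths, c(500, 600))
})

test_that("calibration rejects bad references and shapes", {
  d <- c(2L, 2L, 1L)
  expect_error(calibration_set(array(1, d), array(1, c(2, 2, 2)),
                               array(0, d), 500),
               "identical dimensions")
  same <- array(0.5, d)
  expect_error(calibrate_cube(calibration_set(same, same, same, 500)),
               "degenerate reference")
})

test_that("calibration is invariant to a common positive intensity scale", {
  set.seed(1)
  d <- c(4L, 4L, 3L)
  dark <- array(runif(prod(d), 0, 0.1), d)
  white <- dark + array(runif(prod(d), 0.5, 1), d)
  raw <- dark + array(runif(prod(d), 0, 0.5), d)
  base <- calibrate_cube(calibration_set(raw, white, dark, c(1, 2, 3)))
  for (fac in c(0.25, 3.7, 1e4)) {
    scaled <- calibrate_cube(calibration_set(raw * fac, white * fac,
                                             dark * fac, c(1, 2, 3)))
    expect_equal(scaled$data, base$data, tolerance = 1e-12)
  }
})

test_that("wavelength subsetting keeps the inclusive range in order", {
  wl <- seq(400, 1100, by = 100)
  cube <- hyper_cube(array(seq_along(wl), c(1, 1, length(wl))), wl)
  sub <- subset_wavelengths(cube, 420, 1000)
  expect_equal(sub$wavelengths, seq(500, 1000, by = 100))
  expect_equal(as.vector(sub$data), 2:7)
  expect_equal(subset_wavelengths(cube, 400, 1100)$data, cube$data)
  expect_error(subset_wavelengths(cube, 2000, 2100), "empty wavelength")
  expect_error(subset_wavelengths(cube, 900, 500), "lo_nm")
})

test_that("nearest band uses minimal nm distance, ties to the lower band", {
  cube <- hyper_cube(array(0, c(1, 1, 4)), c(400, 500, 600, 700))
  expect_equal(nearest_band(cube, 505), 2L)
  expect_equal(nearest_band(cube, 550), 2L)  # exact tie -> lower
  expect_equal(nearest_band(cube, 551), 3L)
  expect_equal(nearest_band(cube, 1e4), 4L)
})

test_that("segmentation finds bright seeds and drops speckle", {
  img <- matrix(0.02, 60, 80)
  img <- paint_ellipse(img, c(15, 15), c(6, 5), 0.6)
  img <- paint_ellipse(img, c(15, 55), c(7, 6), 0.55)
  img <- paint_ellipse(img, c(45, 35), c(5, 7), 0.65)
  img[55, 75] <- 0.9  # isolated bright speck
  cube <- hyper_cube(array(img, c(60, 80, 1)), 801)
  m <- segment_seeds(cube, 801, threshold = 0.3, min_area = 20)
  expect_equal(m$n_seeds, 3L)
  m2 <- segment_seeds(cube, 801, threshold = NULL, min_area = 20)  # Otsu
  expect_equal(m2$n_seeds, 3L)
  expect_warning(m0 <- segment_seeds(cube, 801, threshold = 2), "no foreground")
  expect_equal(m0$n_seeds, 0L)
})

test_that("seeds merged by a bright bridge segment as one component", {
  # documented behavior: component filtering does not split merged seeds
  img <- matrix(0.02, 40, 60)
  img <- paint_ellipse(img, c(20, 15), c(6, 5), 0.6)
  img <- paint_ellipse(img, c(20, 45), c(6, 5), 0.6)
  img[20, 15:45] <- 0.6  # 1-px bridge
  cube <- hyper_cube(array(img, c(40, 60, 1)), 801)
  expect_equal(segment_seeds(cube, 801, threshold = 0.3)$n_seeds, 1L)
  img[20, 15:45] <- 0.02  # remove the bridge
  cube <- hyper_cube(array(img, c(40, 60, 1)), 801)
  expect_equal(segment_seeds(cube, 801, threshold = 0.3)$n_seeds, 2L)
})

test_that("mean spectra average the masked pixels band by band", {
  cube <- hyper_cube(array(0.3, c(4, 4, 3)), c(1, 2, 3))
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L; lab[3:4, 3:4] <- 2L
  tab <- mean_spectra(cube, seed_mask(lab))
  expect_equal(unname(tab$spectra), matrix(0.3, 2, 3))

  a <- array(0, c(1, 2, 1)); a[1, 1, 1] <- 0.2; a[1, 2, 1] <- 0.4
  tab2 <- mean_spectra(hyper_cube(a, 700), seed_mask(matrix(1L, 1, 2)))
  expect_equal(unname(tab2$spectra[1, 1]), 0.3)

  empty <- mean_spectra(cube, seed_mask(matrix(0L, 4, 4)))
  expect_equal(nrow(empty$spectra), 0L)
  expect_error(mean_spectra(cube, seed_mask(matrix(0L, 3, 3))), "shape")
})

test_that("mean spectra lie bandwise between the instance min and max", {
  set.seed(7)
  cube <- hyper_cube(array(runif(10 * 10 * 4), c(10, 10, 4)), 1:4)
  lab <- matrix(0L, 10, 10); lab[2:6, 3:8] <- 1L
  tab <- mean_spectra(cube, seed_mask(lab))
  px <- which(lab == 1L)
  flat <- matrix(cube$data, 100, 4)
  expect_true(all(tab$spectra[1, ] >= apply(flat[px, ], 2, min)))
  expect_true(all(tab$spectra[1, ] <= apply(flat[px, ], 2, max)))
})

test_that("segment + mean_spectra recover generating spectra within noise", {
  sp <- scene_spec(n_seeds = 6, image_size = c(70, 110), n_bands = 12,
                   seed_axes_px = c(8, 6), noise_sd = 0.02, seed = 99)
  sc <- generate_seed_scene(sp)
  cube <- calibrate_cube(sc$calibration)
  m <- segment_seeds(cube, 801, threshold = 0.15, min_area = 30)
  expect_equal(m$n_seeds, 6L)
  tab <- mean_spectra(cube, m)
  # match segmented instances to generator seeds by centroid-free trick:
  # generator labels and relabeled components coincide (row-major order)
  areas <- tabulate(m$labels[m$labels > 0])
  for (k in seq_len(6)) {
    envelope <- 3 * sp$noise_sd / sqrt(areas[k])
    expect_true(all(abs(tab$spectra[k, ] - sc$seed_spectra[k, ]) < envelope))
  }
})
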