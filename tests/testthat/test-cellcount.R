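test_that("background subtraction flattens illumination but keeps cell contrast", {
  # uniform image: nothing to remove
  flat <- matrix(0.7, 64, 64)
  out <- subtract_background(flat, radius = 10)
  expect_lt(diff(range(out)), 1 / 255)

  # dark discs on a linear ramp: ramp removed, disc contrast preserved
  # (assessed where the structuring element is fully supported; a border
  # strip of one radius keeps an edge bias, as in any rolling-ball scheme)
  img <- disc_image(cbind(c(40, 90), c(40, 90)), c(5, 5))
  ramp <- matrix(rep(seq(0, 0.12, length.out = 128), each = 128), 128, 128)
  out <- subtract_background(img + ramp, radius = 20)[21:108, 21:108]
  bg_pixels <- out[abs(out) < 0.3]
  expect_lt(diff(range(bg_pixels)), 0.012)           # >= 90% ramp removal
  expect_equal(min(out), -0.6, tolerance = 0.06)     # contrast within 10%

  expect_error(subtract_background(array(0, c(4, 4, 3))), "2-D")
})

test_that("8-bit conversion rescales min-max and flags constant images", {
  x <- matrix(c(0, 127.6, 255), 1, 3)
  expect_equal(to_8bit(x), matrix(c(0L, 128L, 255L), 1, 3))
  expect_equal(to_8bit(matrix(c(0, 0.5, 1), 1, 3)),
               matrix(c(0L, 128L, 255L), 1, 3))
  expect_warning(z <- to_8bit(matrix(5, 2, 2)), "constant")
  expect_equal(z, matrix(0L, 2, 2))
})

test_that("fixed-range thresholding partitions by intensity", {
  expect_equal(sum(threshold_mask(matrix(255L, 4, 4), 0, 200)), 0L)
  expect_equal(sum(threshold_mask(matrix(0L, 4, 4), 0, 200)), 16L)
  half <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  mask <- threshold_mask(half, 0, 200)
  expect_identical(unname(mask), half == 0L)
  expect_error(threshold_mask(half, -1, 200), "<= 255")
  expect_error(threshold_mask(half, 201, 200), "<= 255")
})

test_that("particle analysis uses 8-connectivity and the size filter", {
  expect_equal(nrow(analyze_particles(matrix(FALSE, 10, 10))), 0L)

  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  p <- analyze_particles(sq, 6, 150)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area, 100)
  expect_equal(c(p$row, p$col), c(10.5, 10.5))

  # two discs of area ~80 plus a 3-px speck: speck excluded by min_area
  img <- disc_image(cbind(c(30, 90), c(30, 90)), c(5, 5))
  mask <- img < 0.5
  mask[60, 60:62] <- TRUE
  p2 <- analyze_particles(mask, 6, 150)
  expect_equal(nrow(p2), 2L)
  p3 <- analyze_particles(mask, 1, 150)
  expect_equal(nrow(p3), 3L)

  # diagonal-only contact joins into one particle (8-connectivity)
  diag2 <- matrix(FALSE, 6, 6)
  diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(nrow(analyze_particles(diag2, 1, 10)), 1L)
  expect_equal(analyze_particles(diag2, 1, 10)$area, 2)

  # widening the size window never decreases the count
  set.seed(5)
  rnd <- matrix(runif(400) < 0.3, 20, 20)
  n_narrow <- nrow(analyze_particles(rnd, 3, 10))
  n_wide <- nrow(analyze_particles(rnd, 1, 50))
  expect_gte(n_wide, n_narrow)

  # border exclusion switch
  edge <- matrix(FALSE, 10, 10); edge[1:3, 1:3] <- TRUE
  expect_equal(nrow(analyze_particles(edge, 1, 20)), 1L)
  expect_equal(nrow(analyze_particles(edge, 1, 20,
                                      exclude_border = TRUE)), 0L)
})

test_that("chamber geometry converts counts to cells per litre", {
  cfg <- counting_config()
  expect_equal(counts_to_concentration(0, cfg), 0)
  expect_equal(counts_to_concentration(100, cfg), 1.5625e9)
  cfg2 <- counting_config(dilution_factor = 2)
  expect_equal(counts_to_concentration(100, cfg2),
               2 * counts_to_concentration(100, cfg))
  expect_error(counting_config(threshold_lo = 300), "255")
  expect_error(counting_config(min_area = 0), "min_area")
  expect_error(counting_config(analyzed_area = 0), "positive")
})

test_that("the full pipeline counts synthetic scenes exactly", {
  blank <- synth_scene(scene_config(n_cells = 0, noise_sd = 5 / 255),
                       seed = 2)
  expect_equal(count_pipeline(blank$image)$count, 0L)

  sc <- synth_scene(scene_config(n_cells = 50, noise_sd = 0), seed = 3)
  res <- count_pipeline(sc$image)
  expect_equal(res$count, 50L)
  expect_equal(length(res$particle_areas), res$count)
  expect_equal(res$cells_per_liter,
               counts_to_concentration(50, res$config))

  # adding sub-min_area specks does not change the count
  img <- sc$image
  set.seed(9)
  for (i in 1:5) {
    r <- sample(20:230, 1); cl <- sample(20:230, 1)
    img[r, cl] <- img[r, cl] - 0.6
  }
  expect_equal(count_pipeline(img)$count, 50L)
})

test_that("counting is invariant to translating the scene", {
  centers <- cbind(c(30, 60, 90), c(25, 70, 100))
  radii <- c(4, 5, 3)
  base <- count_pipeline(disc_image(centers, radii))$count
  shifted <- count_pipeline(disc_image(centers + 12, radii))$count
  expect_equal(base, 3L)
  expect_equal(shifted, base)
})

test_that("single-channel images round-trip through files", {
  sc <- synth_scene(scene_config(n_cells = 10), seed = 4)
  p <- tempfile(fileext = ".png")
  EBImage::writeImage(sc$image, p)
  img <- read_cell_image(p)
  expect_equal(dim(img), dim(sc$image))
  expect_equal(count_pipeline(img)$count, 10L)
})
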