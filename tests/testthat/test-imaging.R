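test_that("16-bit integer stacks round-trip bit-identically", {
  f <- withr::local_tempfile(fileext = ".tif")
  vox <- array(sample(0:65535, 4 * 8 * 8, TRUE), c(4, 8, 8))
  write_stack(image_stack(vox, c(0.2, 0.1, 0.1), "ligand"), f)
  rt <- read_stack(f)
  expect_identical(rt$voxels, vox + 0)  # numeric storage, identical values
  expect_identical(rt$voxel_size, c(0.2, 0.1, 0.1))
  expect_identical(rt$channel, "ligand")
})

test_that("a single-slice TIFF reads as a stack with z-extent 1", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(array(7, c(1, 5, 6))), f)
  expect_identical(dim_zyx(read_stack(f)), c(1L, 5L, 6L))
})

test_that("float stacks round-trip at float32 precision", {
  f <- withr::local_tempfile(fileext = ".tif")
  vox <- array(runif(3 * 6 * 6) * 1234.5, c(3, 6, 6))
  write_stack(image_stack(vox), f)
  expect_equal(read_stack(f)$voxels, vox, tolerance = 1e-6)
})

test_that("unsupported or uncalibrated TIFFs give instructive errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(8 * 8 * 3), c(8, 8, 3)), f)  # RGB page
  expect_error(read_stack(f, voxel_size = c(1, 1, 1)),
               class = "acquant_unsupported_format")
  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4), f2)  # no sidecar
  expect_error(read_stack(f2), "voxel_size",
               class = "acquant_missing_calibration")
  f3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 4, 4), matrix(0.1, 5, 5)), f3)
  expect_error(read_stack(f3, voxel_size = c(1, 1, 1)),
               class = "acquant_unsupported_format")
})

test_that("illumination correction is the identity for trivial fields", {
  s <- image_stack(array(runif(4 * 6 * 6, 10, 90), c(4, 6, 6)))
  flat1 <- projection(matrix(1, 6, 6))
  expect_equal(correct_illumination(s, flat1)$voxels, s$voxels)
  # uniform gain cancels through the mean-rescaling
  u <- image_stack(array(42, c(2, 6, 6)))
  expect_equal(correct_illumination(u, projection(matrix(2, 6, 6)))$voxels, u$voxels)
})

test_that("a synthetic vignette field is removed by correction", {
  ny <- 32; nx <- 32
  yy <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny)
  xx <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny)
  vignette_gain <- 1 - 0.4 * (yy^2 + xx^2)   # radial falloff
  truth <- matrix(100, ny, nx)
  raw <- image_stack(array(truth * vignette_gain, c(1, ny, nx)))
  corr <- correct_illumination(raw, projection(vignette_gain))
  cv <- function(m) sd(m) / mean(m)
  expect_lt(cv(corr$voxels[1, , ]), 0.01 * cv(raw$voxels[1, , ]))
  # mean-rescaling preserves the raw image's global mean
  expect_equal(mean(corr$voxels[1, , ]), mean(raw$voxels[1, , ]), tolerance = 1e-6)
})

test_that("non-positive flat-dark pixels abort with a pixel count", {
  s <- image_stack(array(1, c(2, 4, 4)))
  flat <- projection(matrix(1, 4, 4)); dark <- projection(matrix(0, 4, 4))
  dark$pixels[1, 1:3] <- 2
  expect_error(correct_illumination(s, flat, dark), "3 pixel",
               class = "acquant_bad_calibration")
})

test_that("summed projections match per-pixel loop sums", {
  vox <- array(as.numeric(1:(5 * 4 * 3)), c(5, 4, 3))   # ramp stack
  s <- image_stack(vox)
  # k identical slices
  su <- image_stack(array(rep(vox[2, , ], each = 3), c(3, 4, 3)))
  expect_equal(sum_projection(su)$pixels, 3 * vox[2, , ])
  # full-range projection conserves the stack total
  expect_equal(sum(sum_projection(s)$pixels), sum(vox))
  # slab [2, 4) against a naive loop
  pr <- sum_projection(s, c(2L, 4L))
  naive <- matrix(0, 4, 3)
  for (y in 1:4) for (x in 1:3) for (z in 3:4) naive[y, x] <- naive[y, x] + vox[z, y, x]
  expect_identical(pr$pixels, naive)
  expect_identical(pr$provenance$z_range, c(2L, 4L))
  expect_error(sum_projection(s, c(3L, 3L)), class = "acquant_bad_param")
})

test_that("projection is linear in the stack", {
  v1 <- array(runif(4 * 5 * 5), c(4, 5, 5)); v2 <- array(runif(4 * 5 * 5), c(4, 5, 5))
  s1 <- image_stack(v1); s2 <- image_stack(v2)
  lin <- image_stack(2 * v1 + 3 * v2)
  expect_equal(sum_projection(lin)$pixels,
               2 * sum_projection(s1)$pixels + 3 * sum_projection(s2)$pixels)
})

test_that("central-slice windows centre on the focus and truncate with a warning", {
  s <- image_stack(array(0, c(20, 4, 4)))
  expect_identical(central_slices(s, 10, 5), c(8L, 13L))
  expect_warning(zr <- central_slices(s, 0, 5), "truncated")
  expect_identical(zr, c(0L, 3L))
  expect_identical(central_slices(s, 7, 1), c(7L, 8L))
  # even k puts the extra slice below the focus
  expect_identical(central_slices(s, 10, 4), c(8L, 12L))
  expect_error(central_slices(s, 25, 5), class = "acquant_bad_param")
})

test_that("background subtraction recovers a signal over uniform background", {
  sig <- matrix(0, 10, 10); sig[4:6, 4:6] <- 50
  mask <- sig > 0
  noisy <- projection(sig + 7)
  out <- subtract_background(noisy, mask)
  expect_equal(out$pixels, sig)
  expect_equal(out$provenance$background_subtracted, 7)
  # zero image stays zero
  z <- projection(matrix(0, 5, 5))
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(subtract_background(z, m)$pixels, matrix(0, 5, 5))
  expect_error(subtract_background(noisy, matrix(TRUE, 10, 10)),
               class = "acquant_bad_param")
})

test_that("background subtraction is idempotent on its own output", {
  set.seed(1)
  px <- matrix(rexp(400, 1 / 20), 20, 20); px[8:12, 8:12] <- px[8:12, 8:12] + 200
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  once <- subtract_background(projection(px), mask)
  twice <- subtract_background(once, mask)
  expect_equal(twice$pixels, once$pixels)
})
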