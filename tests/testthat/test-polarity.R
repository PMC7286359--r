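make_disk <- function(ny, nx, cy, cx, r, value = 100) {
  yy <- matrix(rep(0:(ny - 1), nx), ny)
  xx <- matrix(rep(0:(nx - 1), each = ny), ny)
  disk <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  list(px = disk * value, disk = disk)
}

test_that("a noiseless disk on zero background segments exactly", {
  d <- make_disk(40, 40, 19.5, 19.5, 10)
  mask <- segment_ac(projection(d$px), c(19.5, 19.5))
  expect_identical(mask$pixels, d$disk)
})

test_that("a seed on empty background fails segmentation", {
  d <- make_disk(60, 60, 15, 15, 8)
  expect_error(segment_ac(projection(d$px), c(50, 50)),
               class = "acquant_segmentation_failure")
  expect_error(segment_ac(projection(matrix(0, 20, 20)), c(10, 10)),
               class = "acquant_segmentation_failure")
})

test_that("segmentation of noisy synthetic ACs overlaps the true footprint", {
  for (s in c(11L, 12L, 13L)) {
    sim <- generate_ac_stack(ac_stack_params(rho_dv = 1.3, seed = s))
    proj <- sum_projection(sim$stack)
    mask <- segment_ac(proj, sim$center_yx)
    jac <- sum(mask$pixels & sim$footprint) / sum(mask$pixels | sim$footprint)
    expect_gte(jac, 0.85)
  }
})

test_that("the polarity index reproduces hand arithmetic and edge conventions", {
  # uniform intensity -> exactly 1
  u <- projection(matrix(5, 6, 6))
  expect_identical(polarity_index(u, matrix(TRUE, 6, 6), c(2.5, 2.5), "dv")$index, 1)
  # 2x2: ventral pixels {4, 6}, dorsal {2, 3} -> 5 / 2.5 = 2
  p <- projection(rbind(c(2, 3), c(4, 6)))
  r <- polarity_index(p, matrix(TRUE, 2, 2), c(0.5, 0.5), "dv")
  expect_identical(r$index, 2)
  expect_identical(r$ventral_mean, 5); expect_identical(r$dorsal_mean, 2.5)
  # pixels exactly on the split line are excluded from both halves
  p3 <- projection(rbind(c(1, 1), c(100, 100), c(3, 3)))
  r3 <- polarity_index(p3, matrix(TRUE, 3, 2), c(1, 0.5), "dv")
  expect_identical(r3$index, 3)
})

test_that("degenerate splits raise distinct error classes", {
  p <- projection(rbind(c(1, 1), c(2, 2)))
  expect_error(polarity_index(p, matrix(TRUE, 2, 2), c(-0.5, 0.5), "dv"),
               class = "acquant_undefined_index")
  pz <- projection(rbind(c(0, 0), c(2, 2)))
  expect_error(polarity_index(pz, matrix(TRUE, 2, 2), c(0.5, 0.5), "dv"),
               class = "acquant_infinite_index")
})

test_that("a noiseless synthetic AC recovers rho_dv within rasterization error", {
  sim <- generate_ac_stack(quiet_params(rho_dv = 1.5, background = 10))
  # on the true footprint, only rasterization separates index from rho
  proj <- sum_projection(sim$stack)
  proj <- subtract_background(proj, sim$footprint)
  r <- polarity_index(proj, sim$footprint, sim$center_yx, "dv")
  expect_equal(r$index, 1.5, tolerance = 0.01)
  expect_equal(polarity_index(proj, sim$footprint, sim$center_yx, "ap")$index,
               1.0, tolerance = 0.01)
  # the full chain including Otsu segmentation stays within 5%
  q <- quantify_ac_polarity(sim$stack, sim$center_yx)
  expect_equal(q$i_dv$index, 1.5, tolerance = 0.05)
})

test_that("the index is invariant to intensity scaling and antisymmetric under reflection", {
  set.seed(7)
  for (i in 1:20) {
    ny <- 9; nx <- 8
    px <- matrix(rexp(ny * nx, 1 / 50), ny, nx)
    mask <- matrix(runif(ny * nx) < 0.7, ny, nx)
    mask[4:6, 4:5] <- TRUE
    cy <- 4  # split on the middle row; reflection about it is exact
    r <- tryCatch(polarity_index(projection(px), mask, c(cy, 3.5), "dv"),
                  acquant_error = function(e) NULL)
    if (is.null(r)) next
    r_scaled <- polarity_index(projection(px * 13.7), mask, c(cy, 3.5), "dv")
    expect_equal(r_scaled$index, r$index, tolerance = 1e-12)
    r_flip <- polarity_index(projection(px[ny:1, ]), mask[ny:1, ], c(cy, 3.5), "dv")
    expect_equal(r_flip$index, 1 / r$index, tolerance = 1e-12)
  }
})

test_that("constant offsets inside the mask pull the index toward 1", {
  sim <- generate_ac_stack(quiet_params(rho_dv = 1.8))
  proj <- sum_projection(sim$stack)
  mask <- segment_ac(proj, sim$center_yx)
  r0 <- polarity_index(proj, mask, sim$center_yx, "dv")$index
  shifted <- projection(proj$pixels + 500)
  r1 <- polarity_index(shifted, mask, sim$center_yx, "dv")$index
  expect_gt(r0, r1)   # background subtraction must precede the index
  expect_gt(r1, 1)
})

test_that("the index equals a naive two-loop computation on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    ny <- sample(4:10, 1); nx <- sample(4:10, 1)
    px <- matrix(rexp(ny * nx, 1 / 30), ny, nx)
    mask <- matrix(runif(ny * nx) < 0.8, ny, nx)
    cy <- runif(1, 0.6, ny - 1.6); cx <- runif(1, 0.6, nx - 1.6)
    res <- tryCatch(polarity_index(projection(px), mask, c(cy, cx), "dv"),
                    acquant_error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$index, oracle_polarity_dv(px, mask, cy), tolerance = 1e-12)
  }
})

test_that("classification against thresholds is strictly greater-than", {
  expect_false(classify_polarized(1.1, 1.1))
  expect_true(classify_polarized(1.3, 1.1))
  expect_true(classify_polarized(1.25, 1.2))
  expect_error(classify_polarized(-1), class = "acquant_bad_param")
})

test_that("fraction_polarized reports exceedance fractions with bootstrap CIs", {
  f <- fraction_polarized(c(1.0, 1.2, 1.3, 1.4), 1.1, n_resamples = 2000, seed = 1)
  expect_equal(f$fraction, 0.75)
  all_hi <- fraction_polarized(c(1.5, 1.6, 1.9), 1.1, n_resamples = 500, seed = 1)
  expect_equal(all_hi$fraction, 1)
  expect_equal(all_hi$ci95, c(1, 1))
  expect_error(fraction_polarized(numeric(0)), class = "acquant_bad_param")
})

test_that("estimated exceedance fraction tracks the true rate", {
  p_true <- 0.9; n <- 200
  set.seed(123)
  indices <- ifelse(runif(n) < p_true, 1.5, 1.0)   # above/below threshold 1.1
  f <- fraction_polarized(indices, 1.1, n_resamples = 1000, seed = 4)
  expect_lt(abs(f$fraction - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("the depolarization cross-tab counts pairs and compares cohorts", {
  coh <- data.frame(animal_id = sprintf("a%d", 1:20),
                    ligand_index = c(rep(1.5, 15), rep(1.0, 5)),
                    pip2_index = c(rep(1.5, 18), rep(1.0, 2)))
  ct <- depolarization_crosstab(coh, reference = coh)
  expect_equal(ct$fisher_p, 1.0)
  expect_equal(sum(ct$table), 20)
  # ligand depolarized but PIP2 polarized in all animals -> off-diagonal = n
  odd <- data.frame(animal_id = sprintf("b%d", 1:12),
                    ligand_index = rep(1.0, 12), pip2_index = rep(1.5, 12))
  ct2 <- depolarization_crosstab(odd)
  expect_equal(unname(ct2$table["depolarized", "polarized"]), 12)
  expect_equal(ct2$both_depolarized, 0)
  # unpaired records are named in the error
  bad <- coh; bad$pip2_index[3] <- NA
  expect_error(depolarization_crosstab(bad), "a3",
               class = "acquant_unpaired_records")
})
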