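make_ramp_plane <- function(spacing, n, coef_x = 2, coef_y = 3) {
  xs <- (seq_len(n) - 1) * spacing
  vals <- outer(xs, xs, function(y, x) coef_x * x + coef_y * y)
  annular_plane(vals, spacing, origin = c(0, 0),
                center = (n - 1) * spacing / 2 * c(1, 1))
}

test_that("resampling is the identity at the target spacing and exact on constants", {
  p <- annular_plane(matrix(runif(100, -100, 400), 10, 10), 1.0)
  expect_identical(resample_plane(p, 1.0)$values, p$values)

  const <- annular_plane(matrix(77, 12, 15), c(0.7, 1.3))
  r <- resample_plane(const, 1.0)
  expect_true(all(abs(r$values - 77) < 1e-10))
  expect_equal(r$spacing, c(1, 1))
})

test_that("cubic-spline resampling reproduces affine ramps to 1e-6 HU", {
  p <- make_ramp_plane(0.7, 64)
  r <- resample_plane(p, 1.0)
  cc <- plane_coords(r)
  expected <- outer(cc$y, cc$x, function(y, x) 2 * x + 3 * y)
  expect_lt(max(abs(r$values - expected)), 1e-6)
  # output grid stays inside the source extent
  src <- plane_coords(p)
  expect_lte(max(cc$x), max(src$x) + 1e-9)
})

test_that("resampling rejects rasters too small for a cubic spline", {
  tiny <- annular_plane(matrix(0, 3, 3), 1.0)
  expect_error(resample_plane(tiny, 0.5), "4 x 4")
})

test_that("clipping centres the annulus, pads with air, and is idempotent", {
  n <- 256
  vals <- matrix(seq_len(n * n), n, n)
  p <- annular_plane(vals, 1.0, origin = c(0, 0),
                     center = (n - 1) / 2 * c(1, 1))
  cl <- clip_plane(p, 128L)
  expect_equal(dim(cl$values), c(128L, 128L))
  expect_false(any(cl$values == -1024))
  # the source pixel nearest the centre sits at 0-based index (64, 64)
  ic <- round((p$center[2] - p$origin[2]) / 1.0)
  expect_equal(cl$values[65, 65], vals[ic + 1, ic + 1])

  small <- annular_plane(matrix(5, 100, 100), 1.0, origin = c(0, 0),
                         center = 49.5 * c(1, 1))
  cs <- clip_plane(small, 128L)
  expect_equal(sum(cs$values == -1024), 128^2 - 100^2)
  # padding forms a ring: 14 columns on each side
  expect_true(all(cs$values[, 1:14] == -1024))
  expect_true(all(cs$values[, 115:128] == -1024))

  expect_identical(clip_plane(cl, 128L), cl)
})

test_that("the annulus centre lands on the raster midpoint at both resolutions", {
  for (seed in 1:5) {
    coh <- generate_cohort(1, seed = seed)
    s <- coh$samples[[1]]
    prep <- prepare_sample(s$plane, s$truth_contour)
    for (p in prep) {
      sp <- p$plane$spacing[1]
      mid_mm <- p$plane$origin + 64 * sp  # 0-based index 64
      expect_true(all(abs(mid_mm - s$plane$center) <= sp / 2 + 1e-9))
    }
  }
})

test_that("mask rasterization follows the pixel-centre even-odd rule", {
  grid <- annular_plane(matrix(0, 20, 20), 1.0, origin = c(0, 0))
  # 10 x 10 mm square with edges at half-pixel offsets -> exactly 100 pixels
  sq <- annulus_contour(rbind(c(0.5, 0.5), c(10.5, 0.5),
                              c(10.5, 10.5), c(0.5, 10.5)))
  m <- rasterize_mask(sq, grid)
  expect_equal(sum(m$values), 100)

  # brute-force point-in-polygon oracle over every pixel centre
  cc <- plane_coords(grid)
  oracle <- outer(cc$y, cc$x, function(y, x) {
    x > 0.5 & x < 10.5 & y > 0.5 & y < 10.5
  })
  expect_identical(m$values, oracle)

  far <- annulus_contour(rbind(c(100, 100), c(110, 100), c(110, 110)))
  expect_false(any(rasterize_mask(far, grid)$values))
})

test_that("rasterized circle area converges to pi r^2 as spacing shrinks", {
  circ <- ellipse_contour(10, 10, n = 1440)
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    n <- round(50 / sp)
    grid <- annular_plane(matrix(0, n, n), sp,
                          origin = -(n - 1) / 2 * sp * c(1, 1))
    abs(mask_area(rasterize_mask(circ, grid)) - pi * 100)
  }, 0)
  expect_lt(errs[3] / (pi * 100), 0.01)
  # finer sampling beats the coarsest grid (pixel-count error is noisy,
  # so strict monotonicity across every step is not required)
  expect_lt(errs[3], errs[1])
})

test_that("mask rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  ell <- ellipse_contour(12, 8, rotation = 0.6, center = c(2, -1))
  n <- 64
  grid <- annular_plane(matrix(0, n, n), 1.0,
                        origin = -(n - 1) / 2 * c(1, 1))
  m <- rasterize_mask(ell, grid)
  cc <- plane_coords(grid)
  pts <- cbind(rep(cc$x, each = n), rep(cc$y, times = n))
  oracle <- mgcv::in.out(rbind(unclass(ell), unclass(ell)[1, ]), pts)
  expect_identical(as.vector(m$values), oracle)
})

test_that("degenerate contours are rejected", {
  grid <- annular_plane(matrix(0, 10, 10), 1.0)
  expect_error(annulus_contour(rbind(c(0, 0), c(1, 1))), "3 distinct")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(annulus_contour(bowtie), "self-intersecting")
  expect_error(rasterize_mask(rbind(c(0, 0), c(1, 1)), grid), "3 distinct")
})

test_that("prepare_sample yields aligned dual-resolution planes and masks", {
  s <- generate_phantom(
    phantom_spec(semi_axis_a = 10, semi_axis_b = 10, noise_sd = 0),
    seed = 4
  )
  prep <- prepare_sample(s$plane, s$truth_contour)
  expect_named(prep, c("r1", "r0.5"))
  for (p in prep) expect_equal(dim(p$plane$values), c(128L, 128L))
  err <- vapply(prep, function(p) {
    abs(mask_area(p$mask) - pi * 100) / (pi * 100)
  }, 0)
  expect_true(all(err < 0.015))
  expect_lt(err["r0.5"], err["r1"])
  # fine plane covers the central quarter of the coarse field of view
  expect_equal(diff(range(plane_coords(prep$r0.5$plane)$x)) /
                 diff(range(plane_coords(prep$r1$plane)$x)),
               0.5, tolerance = 0.02)

  no_ct <- prepare_sample(s$plane)
  expect_null(no_ct$r1$mask)
  expect_equal(dim(no_ct$r0.5$plane$values), c(128L, 128L))
})

test_that("HU standardization clamps and maps to [-1, 1]", {
  expect_equal(standardize_hu(-1024), -1)
  expect_equal(standardize_hu(1500), 1)
  expect_equal(standardize_hu(-5000), -1)
  expect_equal(standardize_hu(9000), 1)
  expect_equal(standardize_hu(238), 0, tolerance = 1e-12)
})
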