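test_that("NIfTI round trip preserves values and geometry", {
  v <- make_grid(shape = c(12L, 10L, 6L), spacing = c(0.977, 0.977, 2.5),
                 origin = c(-5.5, 3.25, -10))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, units = "HU")
  expect_identical(dim(r$values), dim(v$values))
  expect_equal(r$values, v$values, tolerance = 0)
  expect_equal(r$spacing_mm, v$spacing_mm, tolerance = 1e-6)
  expect_equal(r$origin_mm, v$origin_mm, tolerance = 1e-6)

  # binary mask round trip, 1.726 mm isotropic header
  m <- ellipsoid_grid(c(16L, 16L, 16L), rep(1.726, 3), c(0, 0, 0), c(8, 6, 9))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(m, f2)
  r2 <- read_volume(f2, units = "binary")
  expect_identical(r2$values, m$values)
  expect_equal(r2$spacing_mm, rep(1.726, 3), tolerance = 1e-6)
})

test_that("volume I/O rejects malformed input", {
  img2d <- RNifti::asNifti(matrix(rnorm(16), 4, 4))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img2d, f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "cannot read")
  v <- make_grid(shape = c(4L, 4L, 4L))
  suppressWarnings(
    expect_error(write_volume(v, file.path(tempdir(), "no", "such", "dir", "x.nii")),
                 "cannot write"))
  expect_error(volume_grid(array(0, c(2, 2, 2)), spacing_mm = c(1, -1, 1)),
               "positive")
  expect_error(volume_grid(array(0.5, c(2, 2, 2)), spacing_mm = c(1, 1, 1),
                           units = "binary"), "binary")
})

test_that("resampling: identity, constants, extents and mask mode", {
  v <- make_grid(shape = c(10L, 8L, 6L), spacing = c(2, 2, 2.5))
  same <- resample(v, v$spacing_mm, dim(v$values))
  expect_equal(same$values, v$values, tolerance = 1e-12)

  const <- make_grid(shape = c(9L, 9L, 9L), spacing = c(1, 1, 1), fill = 7)
  r <- resample(const, c(0.6, 1.3, 0.9))
  inner <- r$values[2:(dim(r$values)[1] - 1), 2:(dim(r$values)[2] - 1),
                    2:(dim(r$values)[3] - 1)]
  expect_equal(unname(range(inner)), c(7, 7), tolerance = 1e-12)

  # native CT grid to the 1.726 mm common grid: centered, extents as designed
  ct <- volume_grid(array(7, c(512L, 512L, 161L)),
                    spacing_mm = c(0.977, 0.977, 2.5),
                    origin_mm = c(0, 0, 0), units = "HU")
  common <- resample(ct, 1.726, c(256L, 256L, 232L))
  expect_identical(dim(common$values), c(256L, 256L, 232L))
  # shape * spacing arithmetic: 500.2 mm in-plane trimmed to 441.9 mm
  expect_equal(512 * 0.977, 500.224)
  expect_equal(256 * 1.726, 441.856)
  expect_equal(grid_center(common), grid_center(ct), tolerance = 1e-9)
  # interior keeps the constant; nonnegative stays nonnegative
  expect_true(all(common$values >= 0))
  expect_equal(common$values[128, 128, 116], 7, tolerance = 1e-12)

  # mask mode stays binary and requires the binary tag
  m <- ellipsoid_grid(c(20L, 20L, 20L), c(2, 2, 2), c(0, 0, 0), c(12, 9, 14))
  rm <- resample(m, c(1.3, 1.3, 1.3), mode = "mask")
  expect_true(all(rm$values %in% c(0, 1)))
  expect_identical(rm$units, "binary")
  expect_gt(dice_coefficient(resample(rm, c(2, 2, 2), dim(m$values), mode = "mask"),
                             m), 0.9)
  expect_error(resample(make_grid(), c(1, 1, 1), mode = "mask"), "binary")
})

test_that("total activity is conserved under resampling of a smooth volume", {
  sh <- c(40L, 40L, 40L)
  co <- lapply(1:3, function(a) seq(-39, 39, length.out = 40))
  blob <- array(0, dim = sh)
  for (z in 1:40) for (y in 1:40)
    blob[, y, z] <- exp(-(co[[1]]^2 + co[[2]][y]^2 + co[[3]][z]^2) / (2 * 12^2))
  v <- volume_grid(blob * 1e5, spacing_mm = rep(2, 3),
                   origin_mm = c(-39, -39, -39), units = "Bq_per_ml")
  tot0 <- sum(v$values) * voxel_volume_ml(v)
  r <- resample(v, rep(3.1, 3))
  tot1 <- sum(r$values) * voxel_volume_ml(r)
  expect_lt(abs(tot1 - tot0) / tot0, 0.02)
})

test_that("crop and uncrop are inverse on the window interior", {
  v <- make_grid(shape = c(20L, 16L, 12L), spacing = c(1.5, 1.5, 2),
                 origin = c(-10, -8, -6))
  w <- crop_to_window(v, c(8L, 8L, 8L))
  expect_identical(dim(w$values), c(8L, 8L, 8L))
  back <- uncrop(w)
  ci <- attr(w, "crop_info")
  sl <- lapply(1:3, function(a) seq(ci$start[a], ci$start[a] + 7))
  expect_equal(back$values[sl[[1]], sl[[2]], sl[[3]]],
               v$values[sl[[1]], sl[[2]], sl[[3]]])
  expect_equal(back$origin_mm, v$origin_mm)

  # identity when the window equals the volume
  w2 <- crop_to_window(v, dim(v$values))
  expect_equal(w2$values, v$values)
  expect_equal(w2$origin_mm, v$origin_mm)

  # window larger than the volume: zero padding, world coordinates kept
  w3 <- crop_to_window(v, c(26L, 26L, 16L))
  expect_identical(dim(w3$values), c(26L, 26L, 16L))
  b3 <- uncrop(w3)
  expect_equal(b3$values, v$values)

  # mask crop/uncrop restores the mask, outside-window voxels zero
  m <- ellipsoid_grid(c(20L, 16L, 12L), c(1.5, 1.5, 2), c(0, 0, 0), c(6, 5, 6))
  wm <- crop_to_window(m, c(10L, 10L, 10L))
  bm <- uncrop(wm)
  expect_true(all(bm$values[m$values == 0] == 0))
})

test_that("smooth_mask preserves smooth shapes, closes gaps, is idempotent", {
  m <- ellipsoid_grid(c(28L, 28L, 28L), c(2, 2, 2), c(0, 0, 0), c(18, 14, 20))
  s <- smooth_mask(labeled_mask(m))
  expect_gt(dice_coefficient(s, m), 0.99)
  s2 <- smooth_mask(s)
  expect_gt(dice_coefficient(s2, s), 0.99)

  # striped mask (alternating present/absent coronal slices, emulating
  # uninterpolated 2D ROIs) comes back slice-continuous over the kidney span
  stripes <- m$values
  ys <- which(apply(m$values > 0, 2, any))
  stripes[, ys[seq(2, length(ys), by = 2)], ] <- 0
  sm <- smooth_mask(volume_grid(stripes, spacing_mm = m$spacing_mm,
                                origin_mm = m$origin_mm, units = "binary"))
  span <- range(which(apply(sm$grid$values > 0, 2, any)))
  interior <- seq(span[1] + 1, span[2] - 1)
  expect_true(all(vapply(interior, function(y) any(sm$grid$values[, y, ] > 0),
                         logical(1))))

  empty <- volume_grid(array(0, c(6, 6, 6)), spacing_mm = c(1, 1, 1),
                       units = "binary")
  expect_warning(out <- smooth_mask(empty), "empty")
  expect_equal(sum(out$grid$values), 0)
})

test_that("laterality labels follow world-x centroids; small components drop", {
  vals <- array(0, dim = c(30L, 10L, 10L))
  vals[22:27, 4:7, 4:7] <- 1   # larger x index
  vals[3:8, 4:7, 4:7] <- 1     # smaller x index
  m <- labeled_mask(vals, spacing_mm = c(1, 1, 1), origin_mm = c(-15, 0, 0))
  expect_setequal(m$sides, c("left", "right"))
  r <- side_mask(m, "right")
  expect_true(all(which(r, arr.ind = TRUE)[, 1] >= 22))

  # three blobs, two largest survive with max_components = 2
  vals[14:15, 4:5, 4:5] <- 1
  m2 <- labeled_mask(vals, spacing_mm = c(1, 1, 1), max_components = 2)
  expect_length(m2$sides, 2)
  expect_equal(sum(m2$grid$values), sum(vals) - 8)

  # a single blob gets its side from the volume midline
  one <- array(0, dim = c(30L, 10L, 10L))
  one[3:8, 4:7, 4:7] <- 1
  m3 <- labeled_mask(one, spacing_mm = c(1, 1, 1))
  expect_identical(m3$sides, "left")
})
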