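test_that("threshold_mask applies the half-open band and is monotone", {
  vol <- volume_image(array(100, c(4, 4, 4)))
  expect_true(all(threshold_mask(vol, 50)$data))
  expect_warning(excl <- threshold_mask(vol, 50, 100), "empty")
  expect_false(any(excl$data)) # high edge exclusive
  expect_warning(m <- threshold_mask(vol, 300), "empty")
  expect_false(any(m$data))
  # monotone in `low` on a noisy phantom
  ph <- make_resection_volume(phantom_spec(seed = 4L))$volume
  lows <- c(20, 60, 100, 140)
  counts <- vapply(lows, function(l)
    sum(threshold_mask(ph, l)$data), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("phantom bone voxel count is recovered exactly without noise", {
  spec <- phantom_spec(grey_spongious = 200, noise_sd = 0, seed = 2L)
  ph <- make_resection_volume(spec)
  m <- threshold_mask(ph$volume, 100)
  expect_identical(mask_volume(m)$voxels, ph$truth$bone_voxels)
})

test_that("otsu threshold separates bimodal grey populations", {
  set.seed(5)
  n <- 20
  vals <- c(rnorm(4000, 0, 10), rnorm(4000, 200, 10))
  vol <- volume_image(array(vals, c(n, n, n)))
  thr <- otsu_threshold(vol)
  expect_gt(thr, 50)
  expect_lt(thr, 150)
  # exhaustive-search oracle: the returned threshold must achieve the
  # maximal between-class variance (inside a data gap the criterion is
  # constant, so any point of the gap is a valid maximiser)
  vv <- as.vector(vol$data)
  crit <- function(t) {
    w <- mean(vv < t)
    if (w == 0 || w == 1) return(-Inf)
    w * (1 - w) * (mean(vv[vv >= t]) - mean(vv[vv < t]))^2
  }
  best <- max(vapply(sort(unique(round(vv))), crit, 0))
  expect_gt(crit(thr), 0.999 * best)
  # two-voxel edge case and degenerate input
  two <- volume_image(array(c(0, 10, 0, 10, 0, 10, 0, 10), c(2, 2, 2)))
  t2 <- otsu_threshold(two)
  expect_gt(t2, 0)
  expect_lte(t2, 10)
  expect_error(otsu_threshold(volume_image(array(5, c(3, 3, 3)))), "constant")
})

test_that("crop shifts the origin and composes like nested boxes", {
  arr <- array(seq_len(6 * 7 * 8), c(6, 7, 8))
  vol <- volume_image(arr, c(0.5, 1, 2), c(10, 20, 30))
  full <- crop(vol, bounding_box(c(1, 1, 1), c(6, 7, 8)))
  expect_identical(full$data, vol$data)
  expect_identical(full$origin, vol$origin)
  outer <- bounding_box(c(2, 2, 2), c(6, 6, 6))
  inner <- bounding_box(c(2, 1, 2), c(4, 3, 4)) # relative to outer
  once <- crop(crop(vol, outer), inner)
  direct <- crop(vol, bounding_box(c(3, 2, 3), c(5, 4, 5)))
  expect_identical(once$data, direct$data)
  expect_identical(once$origin, direct$origin)
  expect_error(crop(vol, bounding_box(c(1, 1, 1), c(7, 7, 8))), "exceeds")
})

test_that("cropping the container phantom removes all container voxels", {
  spec <- phantom_spec(container = TRUE, noise_sd = 0, seed = 3L)
  ph <- make_resection_volume(spec)
  cropped <- crop(ph$volume, ph$truth$crop_box)
  m <- threshold_mask(cropped, (spec$grey_spongious + spec$grey_background) / 2)
  expect_identical(mask_volume(m)$voxels, ph$truth$bone_voxels)
  # container voxels are gone: nothing at the cortical grey level remains
  expect_false(any(cropped$data >= spec$grey_cortical &
                     cropped$data < spec$grey_sclerotic))
})

test_that("largest_component keeps the big blob and applies the tie rule", {
  d <- c(14, 14, 14)
  a <- array(FALSE, d)
  a[2:11, 2:11, 2:11] <- TRUE # 1000-voxel blob
  speck <- array(FALSE, d)
  speck[13:14, 14, 14] <- TRUE
  speck[14, 13, 14] <- TRUE
  m <- binary_mask(a | speck)
  out <- largest_component(m)
  expect_equal(sum(out$data), 1000L)
  expect_false(out$data[14, 14, 14])
  # single blob is the identity
  solo <- binary_mask(a)
  expect_identical(largest_component(solo)$data, solo$data)
  # two equal blobs: lexicographically smaller minimal index wins
  b <- array(FALSE, d)
  b[8:12, 8, 8] <- TRUE  # min index (8,8,8)
  b[2:6, 9, 9] <- TRUE   # min index (2,9,9) -> lexicographically smaller
  tie <- largest_component(binary_mask(b))
  expect_true(tie$data[2, 9, 9])
  expect_false(tie$data[8, 8, 8])
  # 6 vs 26 connectivity: diagonal touch joins only under 26
  dg <- array(FALSE, c(4, 4, 4))
  dg[1, 1, 1] <- TRUE
  dg[2, 2, 2] <- TRUE
  dg[2, 2, 3] <- TRUE
  expect_equal(sum(largest_component(binary_mask(dg), 26)$data), 3L)
  expect_equal(sum(largest_component(binary_mask(dg), 6)$data), 2L)
  expect_error(largest_component(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("mask_volume does voxel arithmetic and is additive", {
  m <- binary_mask(array(TRUE, c(10, 10, 10)), c(0.5, 0.5, 0.5))
  mv <- mask_volume(m)
  expect_identical(mv$voxels, 1000L)
  expect_equal(mv$mm3, 125)
  empty <- binary_mask(array(FALSE, c(3, 3, 3)), c(0.5, 0.5, 0.5))
  expect_identical(mask_volume(empty)$voxels, 0L)
  expect_equal(mask_volume(empty)$mm3, 0)
  # additivity over disjoint masks
  a <- array(FALSE, c(6, 6, 6)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[5:6, , ] <- TRUE
  s <- mask_volume(binary_mask(a | b, c(0.3, 0.3, 0.3)))
  expect_equal(s$mm3, mask_volume(binary_mask(a, c(0.3, 0.3, 0.3)))$mm3 +
                 mask_volume(binary_mask(b, c(0.3, 0.3, 0.3)))$mm3)
})

test_that("wedge phantom physical volume matches the analytic prism", {
  for (ang in c(0, 3)) {
    spec <- phantom_spec(wedge_angle_deg = ang, noise_sd = 0, seed = 1L)
    ph <- make_resection_volume(spec)
    m <- threshold_mask(ph$volume, 60)
    expect_lt(abs(mask_volume(m)$mm3 / ph$truth$prism_mm3 - 1), 0.03)
  }
})
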