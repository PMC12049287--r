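test_that("sclerosis cut-off follows the upper-third range rule", {
  sl <- matrix(c(0, 300, 150, 100), 2, 2)
  msk <- matrix(TRUE, 2, 2)
  expect_equal(sclerosis_threshold(sl, msk), 200)
  expect_equal(sclerosis_threshold(matrix(c(100, 400, 200, 300), 2, 2), msk), 300)
  expect_error(sclerosis_threshold(matrix(150, 2, 2), msk), "constant")
  # quantile rule at the same fraction is the 2/3 quantile
  vals <- matrix(seq(0, 300, length.out = 16), 4, 4)
  expect_equal(sclerosis_threshold(vals, matrix(TRUE, 4, 4), rule = "quantile"),
               unname(quantile(vals, 2 / 3)))
})

test_that("sclerosis percentage counts pixels and conserves totals", {
  sl <- matrix(c(rep(100, 75), rep(200, 25)), 10, 10)
  msk <- matrix(TRUE, 10, 10)
  res <- sclerosis_percent(sl, msk, 150)
  expect_equal(res$percent, 25)
  expect_equal(res$sclerotic + res$spongious, 100L)
  expect_warning(hi <- sclerosis_percent(sl, msk, 500), "above")
  expect_equal(hi$percent, 0)
  expect_error(sclerosis_percent(sl, matrix(FALSE, 10, 10), 150), "empty")
})

test_that("percentage is invariant to affine grey rescaling", {
  spec <- phantom_spec(sclerotic_fraction = 0.2, seed = 8L)
  sl <- make_sclerosis_slice(spec)
  p0 <- sclerosis_percent(sl$slice, sl$slice_mask,
                          sclerosis_threshold(sl$slice, sl$slice_mask))$percent
  resc <- sl$slice * 3.7 + 120
  p1 <- sclerosis_percent(resc, sl$slice_mask,
                          sclerosis_threshold(resc, sl$slice_mask))$percent
  expect_equal(p1, p0)
})

test_that("generator fractions are recovered within one percentage point", {
  errs <- vapply(seq(0, 0.4, 0.05), function(f) {
    spec <- phantom_spec(sclerotic_fraction = f, seed = round(100 * f) + 3L)
    sl <- make_sclerosis_slice(spec)
    thr <- sclerosis_threshold(sl$slice, sl$slice_mask)
    res <- sclerosis_percent(sl$slice, sl$slice_mask, thr)
    res$percent - 100 * sl$true_fraction
  }, 0)
  expect_lt(mean(abs(errs)), 1)
  # the targeted f cases from the phantom grey model
  for (f in c(0, 0.1, 0.3)) {
    spec <- phantom_spec(sclerotic_fraction = f, seed = 31L + round(10 * f))
    sl <- make_sclerosis_slice(spec)
    thr <- if (f > 0) sclerosis_threshold(sl$slice, sl$slice_mask) else
      max(sl$slice[sl$slice_mask]) # threshold needs >= 2 values; guard covers f=0
    res <- sclerosis_percent(sl$slice, sl$slice_mask,
                             if (f > 0) thr else
                               sclerosis_threshold(sl$slice, sl$slice_mask))
    expect_lt(abs(res$percent - 100 * sl$true_fraction), 1)
  }
})

test_that("rotation correction recovers a known tilt", {
  spec <- phantom_spec(tilt_deg = 5, noise_sd = 5, seed = 6L)
  ph <- make_resection_volume(spec)
  mask <- largest_component(threshold_mask(ph$volume, 60))
  rc <- rotation_correct(ph$volume, mask)
  expect_lt(abs(rc$angle_deg - 5), 0.5)
  # already-aligned phantom: near-identity, grey values almost untouched
  ph0 <- make_resection_volume(phantom_spec(noise_sd = 5, seed = 6L))
  mask0 <- largest_component(threshold_mask(ph0$volume, 60))
  rc0 <- rotation_correct(ph0$volume, mask0)
  expect_lt(rc0$angle_deg, 0.1)
  expect_equal(rc0$volume$data, ph0$volume$data, tolerance = 1e-10,
               ignore_attr = TRUE)
  # tiny mask cannot support a plane fit
  tiny <- array(FALSE, dim(ph0$volume$data))
  tiny[3, 3, 3:5] <- TRUE
  expect_error(rotation_correct(ph0$volume,
                                binary_mask(tiny, ph0$volume$spacing,
                                            ph0$volume$origin)),
               "16")
})

test_that("most distal slice respects the ragged-face guard", {
  spec <- phantom_spec(noise_sd = 0, seed = 2L)
  ph <- make_resection_volume(spec)
  mask <- largest_component(threshold_mask(ph$volume, 60))
  sl <- most_distal_slice(ph$volume, mask)
  expect_equal(sl$index, ph$truth$distal_slice_index)
  expect_true(any(sl$slice_mask))
  # make the distal face ragged: keep only a sliver of the first bone slice
  ragged <- mask
  k <- sl$index
  keep <- array(TRUE, dim(ragged$data))
  keep[, 1:(dim(keep)[2] - 5), k] <- FALSE
  ragged$data[, , k] <- ragged$data[, , k] & keep[, , k]
  guard <- most_distal_slice(ph$volume, ragged, min_area_fraction = 1.0)
  expect_gt(guard$index, k)
  # single-slice specimen returns that slice
  single <- array(FALSE, c(8, 8, 4)); single[3:6, 3:6, 2] <- TRUE
  sm <- binary_mask(single)
  sv <- volume_image(array(1.0 * single, dim(single)))
  expect_equal(most_distal_slice(sv, sm)$index, 2L)
})

test_that("class-separation statistic distinguishes unimodal from bimodal", {
  set.seed(13)
  uni <- rnorm(4000, 120, 15)
  expect_lt(resectfit:::grey_class_separation(uni), 4)
  expect_gt(resectfit:::grey_class_separation(uni), 2)   # forced-split floor
  bi <- c(rnorm(3800, 120, 15), rnorm(200, 280, 15))
  expect_gt(resectfit:::grey_class_separation(bi), 8)
  expect_equal(resectfit:::grey_class_separation(rep(c(0, 300), 50)), Inf)
})
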