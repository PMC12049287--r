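test_that("signed distance is zero for identical meshes", {
  tray <- make_implant_mesh(phantom_spec())
  dm <- signed_distance(tray, tray, voxel_size = 1)
  expect_lt(max(abs(dm$values)), 1e-12)
})

test_that("parallel flat patch sits at +2 voxels above a plate", {
  plate <- triangle_mesh(
    cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10), 0),
    rbind(c(1, 2, 3), c(1, 3, 4))) # counter-clockwise from +z: normal +z
  patch <- triangle_mesh(
    cbind(c(-2, 2, 2, -2), c(-2, -2, 2, 2), 2),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  dm <- signed_distance(patch, plate, unit = "voxel", voxel_size = 1)
  expect_equal(dm$values, rep(2, 4), tolerance = 1e-12)
  below <- apply_transform(patch, rigid_transform(diag(3), c(0, 0, -4)))
  dmb <- signed_distance(below, plate, voxel_size = 1)
  expect_equal(dmb$values, rep(-2, 4), tolerance = 1e-12)
  # unit conversion
  dmm <- signed_distance(patch, plate, unit = "mm", voxel_size = 0.5)
  expect_equal(dmm$values, rep(2, 4), tolerance = 1e-12)
  dvx <- signed_distance(patch, plate, unit = "voxel", voxel_size = 0.5)
  expect_equal(dvx$values, rep(4, 4), tolerance = 1e-12)
})

test_that("distances match the exhaustive brute-force oracle on random meshes", {
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    target <- random_soup(nv = sample(10:30, 1), nf = sample(12:40, 1))
    pts <- matrix(runif(3 * 20, -12, 12), ncol = 3)
    probe <- triangle_mesh(pts, t(replicate(10, sample.int(20, 3))))
    dm <- signed_distance(probe, target, unit = "mm")
    oracle <- brute_mesh_dist(pts, target)
    worst <- max(worst, max(abs(abs(dm$values) - oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("sign classification is correct on closed meshes", {
  cube <- unit_cube_mesh()
  pts <- rbind(c(0.5, 0.5, 0.5),   # inside -> negative
               c(2, 0.5, 0.5),     # outside a face
               c(1.5, 1.5, 0.5),   # closest to an edge
               c(1.4, 1.4, 1.4))   # closest to a corner
  probe <- triangle_mesh(pts, matrix(c(1, 2, 3, 1, 3, 4), 2, byrow = TRUE))
  dm <- signed_distance(probe, cube, unit = "mm")
  expect_lt(dm$values[1], 0)
  expect_gt(dm$values[2], 0)
  expect_gt(dm$values[3], 0)
  expect_gt(dm$values[4], 0)
  expect_equal(abs(dm$values[1]), 0.5, tolerance = 1e-12)
  expect_equal(dm$values[3], sqrt(0.5), tolerance = 1e-12)
})

test_that("distance summary uses abs mean/sd and signed max", {
  dm <- structure(list(values = c(1, 3), mm = c(1, 3), unit = "voxel",
                       voxel_size = 1, n_vertices = 2), class = "distance_map")
  s <- summarize_distances(dm)
  expect_equal(s$mean_abs, 2)
  expect_equal(s$sd_abs, sd(c(1, 3))) # sample convention
  expect_equal(s$max_signed, 3)
  zero <- structure(list(values = numeric(3), mm = numeric(3), unit = "voxel",
                         voxel_size = 1, n_vertices = 3), class = "distance_map")
  sz <- summarize_distances(zero)
  expect_equal(unlist(sz[c("mean_abs", "sd_abs", "max_signed")]),
               c(mean_abs = 0, sd_abs = 0, max_signed = 0))
})

test_that("binning follows the eight-band colour code and conserves counts", {
  mk <- function(v) structure(list(values = v, mm = v, unit = "voxel",
                                   voxel_size = 1, n_vertices = length(v)),
                              class = "distance_map")
  b <- bin_distances(mk(c(0.5, 7.5, 8.2, -0.3, 1.0, 6.999)))
  expect_equal(unname(b$counts["Light Blue"]), 1L)
  expect_equal(unname(b$counts["Pink"]), 1L)
  expect_equal(unname(b$counts["Dark Blue"]), 1L)  # 1.0 -> [1,2)
  expect_equal(unname(b$counts["Orange"]), 1L)     # 6.999 -> [6,7)
  expect_equal(b$overflow, 1L)
  expect_equal(b$negative, 1L)
  expect_equal(sum(b$counts) + b$overflow + b$negative, b$total)
  # property: conservation on random maps
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(200, 3, 4)
    bb <- bin_distances(mk(v))
    expect_equal(sum(bb$counts) + bb$overflow + bb$negative, 200L)
  }
  mmmap <- structure(list(values = 1, mm = 1, unit = "mm", voxel_size = 1,
                          n_vertices = 1), class = "distance_map")
  expect_error(bin_distances(mmmap), "voxel")
})

test_that("renders are deterministic and cover the six standard views", {
  w <- wedge_report(3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_views(w$bone, w$tray, w$dm, d1, width = 120, height = 120)
  p2 <- render_views(w$bone, w$tray, w$dm, d2, width = 120, height = 120)
  expect_length(p1, 6L)
  expect_setequal(basename(p1),
                  paste0("view_", c("anterior", "posterior", "lateral",
                                    "oblique_left", "oblique_right",
                                    "proximal"), ".png"))
  for (k in seq_along(p1))
    expect_identical(readBin(p1[k], "raw", file.size(p1[k])),
                     readBin(p2[k], "raw", file.size(p2[k])))
  bad <- w$dm
  bad$values <- numeric(0)
  expect_error(render_views(w$bone, w$tray, bad, d1), "match|empty")
})
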