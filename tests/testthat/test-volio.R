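test_that("integer volumes round-trip exactly through NIfTI and MetaImage", {
  arr <- array(sample.int(1000, 2 * 3 * 4, replace = TRUE), c(4, 3, 4))
  vol <- volume_image(arr, c(0.5, 0.7, 1.2), c(1, -2, 3), c("AP", "ML", "PD"))
  for (ext in c(".nii.gz", ".nii", ".mha")) {
    p <- withr::local_tempfile(fileext = ext)
    write_volume(vol, p)
    back <- read_volume(p)
    expect_equal(back$data, arr, ignore_attr = TRUE, label = ext)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
    expect_identical(back$axes, vol$axes)
  }
})

test_that("float volumes round-trip within machine precision", {
  arr <- array(rnorm(60), c(3, 4, 5))
  vol <- volume_image(arr)
  p <- withr::local_tempfile(fileext = ".mha")
  write_volume(vol, p)
  expect_equal(read_volume(p)$data, arr, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("synthetic DICOM series reads with correct spacing and values", {
  arr <- array(sample.int(500, 6 * 5 * 3, replace = TRUE), c(6, 5, 3))
  vol <- volume_image(arr, c(0.2, 0.2, 0.2), c(0, 0, 0))
  d <- withr::local_tempdir()
  resectfit:::write_dicom_series(vol, d)
  back <- read_volume(d)
  expect_equal(back$spacing, c(0.2, 0.2, 0.2))
  expect_equal(back$data, arr, ignore_attr = TRUE)
})

test_that("volume reader rejects bad inputs", {
  expect_error(read_volume("/nonexistent/file.nii"), "no such")
  d <- withr::local_tempdir()
  expect_error(read_volume(d), "empty DICOM")
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", p)
  expect_error(read_volume(p), "unrecognized")
  # non-uniform DICOM slice spacing beyond 1%
  arr <- array(1L, c(4, 4, 3))
  vol <- volume_image(arr, c(1, 1, 1))
  d2 <- withr::local_tempdir()
  resectfit:::write_dicom_series(vol, d2)
  # rewrite slice 3 with a shifted position
  vol2 <- volume_image(arr, c(1, 1, 1.3), c(0, 0, 0))
  resectfit:::write_dicom_series(vol2, withr::local_tempdir()) # sanity
  bad <- volume_image(array(1L, c(4, 4, 1) + c(0, 0, 1)), c(1, 1, 1), c(0, 0, 2.4))
  resectfit:::write_dicom_series(bad, d2) # overwrites slices 1-2 at z = 2.4+
  expect_error(read_volume(d2), "spacing|positions")
})

test_that("unit-cube STL welds to 8 vertices and 12 faces", {
  cube <- unit_cube_mesh()
  p <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, p)
  back <- read_mesh(p)
  expect_equal(nrow(back$vertices), 8L)
  expect_equal(nrow(back$faces), 12L)
  expect_true(resectfit:::mesh_is_closed(back))
})

test_that("meshes round-trip through STL (binary + ascii), PLY and OBJ", {
  tray <- make_implant_mesh(phantom_spec())
  ply <- withr::local_tempfile(fileext = ".ply")
  stl <- withr::local_tempfile(fileext = ".stl")
  stla <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tray, ply)
  from_ply <- read_mesh(ply)
  expect_equal(from_ply$vertices, tray$vertices, tolerance = 1e-12)
  write_mesh(from_ply, stl)
  from_stl <- read_mesh(stl)
  # STL stores float32: vertex sets match to float precision, up to reordering
  expect_equal(sort(round(from_stl$vertices, 5)), sort(round(tray$vertices, 5)),
               tolerance = 1e-5)
  expect_true(resectfit:::mesh_is_closed(from_stl))
  write_mesh(tray, stla, ascii = TRUE)
  from_ascii <- read_mesh(stla)
  expect_equal(nrow(from_ascii$vertices), nrow(tray$vertices))
  # OBJ reader
  obj <- withr::local_tempfile(fileext = ".obj")
  cube <- unit_cube_mesh()
  writeLines(c(sprintf("v %g %g %g", cube$vertices[, 1], cube$vertices[, 2],
                       cube$vertices[, 3]),
               sprintf("f %d %d %d", cube$faces[, 1], cube$faces[, 2],
                       cube$faces[, 3])), obj)
  expect_equal(read_mesh(obj)$vertices, cube$vertices)
})

test_that("mesh writers are byte-stable and reject bad input", {
  tray <- make_implant_mesh(phantom_spec())
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tray, p1)
  write_mesh(tray, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  trunc <- withr::local_tempfile(fileext = ".stl")
  writeBin(readBin(p1, "raw", 60), trunc)
  expect_error(read_mesh(trunc), "truncated|corrupt")
  expect_error(write_mesh(tray, withr::local_tempfile(fileext = ".xyz")),
               "unsupported")
  expect_error(triangle_mesh(matrix(0, 0, 3), matrix(1L, 1, 3)), "no vertices")
})

test_that("transform sidecar files round-trip", {
  tr <- rigid_transform(resectfit:::rotation_about_axis(c(1, 2, 3), 33),
                        c(0.1, -2, 5))
  p <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, p)
  back <- read_transform(p)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tr$translation, tolerance = 1e-12)
})

test_that("pipeline config round-trips through YAML and validates", {
  cfg <- pipeline_config(threshold_mode = "fixed", fixed_threshold = 70,
                         icp_trim_fraction = 0.2, seed = 9L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back[names(back) != "fixed_threshold"],
               cfg[names(cfg) != "fixed_threshold"])
  expect_equal(back$fixed_threshold, 70)
  expect_error(pipeline_config(ap_split_fraction = 1.2), "fractions")
  expect_error(pipeline_config(threshold_mode = "fixed"), "fixed_threshold")
})
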