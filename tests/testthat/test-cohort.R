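test_that("implant voxel volume divides the mesh volume by the voxel cube", {
  cube <- unit_cube_mesh()
  expect_equal(implant_voxel_volume(cube, 1)$voxels, 1)
  box <- make_implant_mesh(phantom_spec(ml_width = 25, ap_depth = 40,
                                        thickness_mm = 3, corner_radius_mm = 0))
  expect_equal(implant_voxel_volume(box, 0.5)$voxels, 24000, tolerance = 1e-9)
  tray <- make_implant_mesh(phantom_spec())
  expect_equal(implant_voxel_volume(tray, 0.5)$voxels,
               mesh_metrics(tray)$volume / 0.125)
  open <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(suppressWarnings(implant_voxel_volume(open, 1)), "closed")
})

test_that("welch_t matches the closed-form formula and stats::t.test", {
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(4:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(4:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- welch_t(a, b)
    # independent closed-form evaluation
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    tt <- (mean(a) - mean(b)) / se
    df <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                    (var(b) / length(b))^2 / (length(b) - 1))
    expect_equal(w$t, tt, tolerance = 1e-10)
    expect_equal(w$df, df, tolerance = 1e-10)
    expect_equal(w$p, 2 * pt(-abs(tt), df), tolerance = 1e-10)
    # cross-check against the reference implementation
    ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  shifted <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("run_specimen reproduces phantom truth and is deterministic", {
  spec <- phantom_spec(wedge_angle_deg = 3, seed = 21L)
  ph <- make_resection_volume(spec)
  tray <- make_implant_mesh(spec)
  r1 <- run_specimen(ph$volume, tray, id = "p1", group = "0deg")
  r2 <- run_specimen(ph$volume, tray, id = "p1", group = "0deg")
  expect_identical(resectfit:::specimen_result_row(r1),
                   resectfit:::specimen_result_row(r2))
  # wedge phantom: medial totals exceed central totals
  expect_gt(r1$compartments$totals[["AMM"]], r1$compartments$totals[["AMC"]])
  expect_gt(r1$compartments$totals[["PMM"]], r1$compartments$totals[["PMC"]])
  expect_lt(r1$compartments$quotient, 1)
  # sclerosis close to generator truth
  expect_lt(abs(r1$sclerosis$percent - 100 * ph$truth$sclerotic_fraction), 1.5)
  # volume ratio invariant
  expect_equal(r1$volume_ratio, r1$volume_bone_voxels / r1$volume_implant_voxels,
               tolerance = 1e-9)
  # rectangular phantom: near-noise mismatch
  ph0 <- make_resection_volume(phantom_spec(wedge_angle_deg = 0, seed = 22L))
  r0 <- run_specimen(ph0$volume, make_implant_mesh(phantom_spec(seed = 22L)),
                     id = "p0", group = "3deg")
  expect_lt(r0$compartments$total_mismatch, 0.6)
})

test_that("run_specimen names the failing stage", {
  err <- tryCatch(run_specimen("/does/not/exist.nii", "also-missing.stl"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "segment-input")
})

test_that("cohort table aggregates groups with Welch p-values", {
  spec0 <- phantom_spec(wedge_angle_deg = 3, noise_sd = 10)
  spec3 <- phantom_spec(wedge_angle_deg = 0, noise_sd = 10)
  coh <- make_cohort(3, spec0, spec3, seed = 31)
  results <- lapply(coh, function(s)
    run_specimen(s$volume, s$implant, id = s$id, group = s$group))
  tab <- build_cohort_table(results)
  expect_s3_class(tab, "cohort_table")
  expect_true(all(c("metric", "all_mean", "mean_0deg", "mean_3deg", "p") %in%
                    names(tab)))
  expect_true(all(tab$all_sd >= 0, na.rm = TRUE))
  # the All column is the n-weighted mean of group means (weights = number
  # of specimens contributing a value to that metric)
  rows <- lapply(results, resectfit:::specimen_result_row)
  grp <- vapply(rows, function(r) r$group, "")
  for (m in tab$metric) {
    v <- vapply(rows, function(r) as.numeric(r[[m]]), 0)
    n0 <- sum(!is.na(v[grp == "0deg"]))
    n3 <- sum(!is.na(v[grp == "3deg"]))
    i <- which(tab$metric == m)
    recomputed <- (tab$mean_0deg[i] * n0 + tab$mean_3deg[i] * n3) / (n0 + n3)
    expect_equal(tab$all_mean[i], recomputed, tolerance = 1e-9, label = m)
  }
  # identical groups give p = 1 for every finite metric
  dup <- results[c(1, 2, 3, 1, 2, 3)]
  for (i in 4:6) dup[[i]]$group <- "3deg"
  tab2 <- build_cohort_table(dup)
  expect_true(all(abs(tab2$p - 1) < 1e-12, na.rm = TRUE))
  # single group: warning, no p column
  expect_warning(tab3 <- build_cohort_table(results[1:3]), "single group")
  expect_false("p" %in% names(tab3))
  # constant metric has zero sd
  expect_true(all(tab2$sd_0deg[tab2$metric == "volume_implant_voxels"] >= 0))
})

test_that("cohort manifest runner writes per-specimen and cohort outputs", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(wedge_angle_deg = 3, seed = 41L)
  ph <- make_resection_volume(spec)
  vol_path <- file.path(dir, "vol.nii.gz")
  write_volume(ph$volume, vol_path)
  tray_path <- file.path(dir, "tray.stl")
  write_mesh(make_implant_mesh(spec), tray_path)
  man <- file.path(dir, "manifest.csv")
  write.csv(data.frame(id = c("a", "b"), group = c("g1", "g2"),
                       volume_path = vol_path, implant_path = tray_path),
            man, row.names = FALSE)
  out <- file.path(dir, "out")
  res <- suppressWarnings(run_cohort(man, out_dir = out))
  expect_length(res$results, 2L)
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "a", "a_result.json")))
  # intermediates re-readable
  mask <- read_volume(file.path(out, "a", "a_mask.nii.gz"))
  expect_s3_class(mask, "volume_image")
  expect_gt(sum(mask$data), 0)
  tr <- read_transform(file.path(out, "a", "a_transform.txt"))
  expect_s3_class(tr, "rigid_transform")
})
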