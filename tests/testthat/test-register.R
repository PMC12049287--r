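test_that("rigid transforms form a group with verified invariants", {
  set.seed(3)
  rand_tr <- function() {
    rigid_transform(resectfit:::rotation_about_axis(rnorm(3), runif(1, 0, 180)),
                    rnorm(3, 0, 10))
  }
  for (i in 1:10) {
    t1 <- rand_tr(); t2 <- rand_tr(); t3 <- rand_tr()
    # orthonormality / determinant enforced by the constructor
    expect_lt(max(abs(crossprod(t1$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(t1$rotation) - 1), 1e-9)
    # compose(t, invert(t)) = identity
    id <- compose_transform(t1, invert_transform(t1))
    expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(id$translation)), 1e-9)
    # associativity against the 4x4 homogeneous-matrix oracle
    hom <- function(t) rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
    left <- compose_transform(compose_transform(t1, t2), t3)
    expect_equal(hom(left), hom(t1) %*% hom(t2) %*% hom(t3), tolerance = 1e-9)
  }
  expect_equal(invert_transform(rigid_transform())$rotation, diag(3))
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
})

test_that("apply_transform moves vertices as R v + t", {
  cube <- unit_cube_mesh()
  expect_equal(apply_transform(cube, rigid_transform()), cube)
  rz <- rigid_transform(resectfit:::rotation_about_axis(c(0, 0, 1), 90))
  moved <- apply_transform(cube, rz)
  # (1,0,0) -> (0,1,0)
  i <- which(apply(cube$vertices, 1, function(v) all(v == c(1, 0, 0))))
  expect_equal(moved$vertices[i, ], c(0, 1, 0), tolerance = 1e-12)
  tr <- rigid_transform(resectfit:::rotation_about_axis(c(1, 1, 0), 37), c(1, 2, 3))
  back <- apply_transform(apply_transform(cube, tr), invert_transform(tr))
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-9)
})

test_that("initial_align recovers pose and matches centroids", {
  tray <- make_implant_mesh(phantom_spec())
  # self-alignment is the identity
  self <- initial_align(tray, tray)
  expect_lt(resectfit:::rotation_angle_deg(self$rotation), 1e-4)
  expect_lt(max(abs(self$translation)), 1e-6)
  # known perturbation about a principal axis
  tr <- rigid_transform(resectfit:::rotation_about_axis(c(0, 1, 0), 15),
                        c(5, -4, 3))
  moved <- apply_transform(tray, tr)
  rec <- initial_align(moved, tray)
  err <- compose_transform(rec, tr)
  expect_lt(resectfit:::rotation_angle_deg(err$rotation), 1)
  expect_lt(sqrt(sum(err$translation^2)), 0.5)
  # near-spherical mesh: rotation arbitrary but centroid matched
  sph <- extract_surface(ball_mask(8))
  off <- apply_transform(sph, rigid_transform(diag(3), c(7, 7, 7)))
  al <- initial_align(off, sph)
  moved_c <- resectfit:::mesh_centroid(apply_transform(off, al))
  expect_equal(moved_c, resectfit:::mesh_centroid(sph), tolerance = 1e-4)
  # coplanar mesh is degenerate
  flat <- triangle_mesh(cbind(runif(9), runif(9), 0),
                        matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE))
  expect_error(initial_align(flat, tray), "coplanar|degenerate")
})

test_that("icp is exact on self-registration", {
  tray <- make_implant_mesh(phantom_spec())
  reg <- icp(tray, tray, init = rigid_transform())
  expect_lt(reg$rms, 1e-9)
  expect_lte(reg$iterations, 2L)
})

test_that("trimmed icp recovers seeded perturbations of the tray", {
  tray <- make_implant_mesh(phantom_spec())
  set.seed(20)
  ok <- 0L
  for (s in 1:20) {
    tr <- rigid_transform(
      resectfit:::rotation_about_axis(rnorm(3), runif(1, 0, 20)),
      runif(3, -1, 1) * 10 / sqrt(3))
    moved <- apply_transform(tray, tr)
    reg <- icp(moved, tray)
    err <- compose_transform(reg$transform, tr)
    good <- resectfit:::rotation_angle_deg(err$rotation) < 0.5 &&
      sqrt(sum(err$translation^2)) < 0.1
    ok <- ok + good
    # accepted-iteration RMS sequence is non-increasing
    expect_true(all(diff(reg$rms_history) <= 1e-12))
    expect_lte(reg$iterations, 50L)
  }
  expect_gte(ok, 19L)
})

test_that("icp rejects non-finite vertices", {
  tray <- make_implant_mesh(phantom_spec())
  bad <- tray
  bad$vertices[1, 1] <- NaN
  expect_error(icp(bad, tray, init = rigid_transform()), "non-finite")
})
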