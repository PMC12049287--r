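# Shared in-code fixtures: digitised ball masks, analytic meshes, random
# triangle soups, and an independent point-to-triangle distance oracle.

# digitised ball of radius r (voxels) on an n^3 grid
ball_mask <- function(r = 15, n = 2 * r + 10, spacing = c(1, 1, 1)) {
  cc <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  data <- array((g$i - cc)^2 + (g$j - cc)^2 + (g$k - cc)^2 <= r^2, c(n, n, n))
  binary_mask(data, spacing)
}

# axis-aligned unit cube [0,1]^3 as 12 outward-oriented triangles
unit_cube_mesh <- function(origin = c(0, 0, 0), edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  v <- sweep(v * edge, 2, origin, "+")
  # faces (1-based into the expand.grid order), outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6)    # x = 1 (+x)
  )
  triangle_mesh(v, f)
}

# random triangle soup with <= nv vertices (valid faces, no degenerates)
random_soup <- function(nv = 30, nf = 40, scale = 10) {
  v <- matrix(runif(nv * 3, -scale, scale), ncol = 3)
  f <- t(replicate(nf, sample.int(nv, 3)))
  triangle_mesh(v, f)
}

# independent closest-distance oracle: point to one triangle, solved by
# candidate enumeration (plane projection if its barycentrics are all
# non-negative, else the three edge segments), written without reference to
# the package's C++ region analysis
point_tri_dist_oracle <- function(p, a, b, c_) {
  seg <- function(p, q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d * d)
    t <- max(0, min(1, t))
    sqrt(sum((p - (q0 + t * d))^2))
  }
  n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
         (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
         (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
  cands <- c(seg(p, a, b), seg(p, b, c_), seg(p, c_, a))
  nn <- sum(n * n)
  if (nn > 0) {
    # barycentric coordinates of the in-plane projection
    q <- p - sum((p - a) * n) / nn * n
    den <- nn
    la <- sum(n * c((c_ - b)[2] * (q - b)[3] - (c_ - b)[3] * (q - b)[2],
                    (c_ - b)[3] * (q - b)[1] - (c_ - b)[1] * (q - b)[3],
                    (c_ - b)[1] * (q - b)[2] - (c_ - b)[2] * (q - b)[1])) / den
    lb <- sum(n * c((a - c_)[2] * (q - c_)[3] - (a - c_)[3] * (q - c_)[2],
                    (a - c_)[3] * (q - c_)[1] - (a - c_)[1] * (q - c_)[3],
                    (a - c_)[1] * (q - c_)[2] - (a - c_)[2] * (q - c_)[1])) / den
    lc <- 1 - la - lb
    if (la >= 0 && lb >= 0 && lc >= 0) cands <- c(cands, sqrt(sum((p - q)^2)))
  }
  min(cands)
}

# brute-force distance from each point to a whole mesh via the oracle
brute_mesh_dist <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(t)
      point_tri_dist_oracle(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ]),
      0))
  })
}

# quick wedge-phantom pipeline at the generator's ground-truth pose
wedge_report <- function(angle, spacing = 0.5, seed = 1L) {
  spec <- phantom_spec(wedge_angle_deg = angle, spacing_mm = spacing,
                       seed = seed)
  ph <- make_resection_volume(spec)
  tray <- make_implant_mesh(spec)
  thr <- otsu_threshold(ph$volume)
  mask <- largest_component(threshold_mask(ph$volume, thr))
  bone <- extract_surface(mask)
  dm <- signed_distance(bone, tray, voxel_size = spacing)
  rep <- totals_and_quotient(max_elevation(partition_compartments(bone, tray), dm))
  list(spec = spec, truth = ph$truth, mask = mask, bone = bone, tray = tray,
       dm = dm, report = rep)
}
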