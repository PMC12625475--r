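test_that("PCA plane fitting recovers exact and noisy planes", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_plane_pca(sq)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$offset, 0, tolerance = 1e-12)

  tri <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))  # x + y + z = 3
  pl3 <- fit_plane_pca(tri)
  expect_equal(pl3$normal, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(pl3$offset, sqrt(3), tolerance = 1e-9)

  set.seed(1)
  pts <- cbind(runif(200, 0, 10), runif(200, 0, 10), runif(200, -0.01, 0.01))
  pln <- fit_plane_pca(pts)
  angle <- acos(min(1, abs(pln$normal[3]))) * 180 / pi
  expect_lt(angle, 0.2)

  # residual RMS is zero for exactly coplanar points
  cop <- cbind(runif(50), runif(50), 0.7 * runif(50))
  cop[, 3] <- 2 * cop[, 1] - cop[, 2] + 1
  plc <- fit_plane_pca(cop)
  expect_lt(sqrt(mean(stentforge:::plane_distance(plc, cop)^2)), 1e-10)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_plane_pca(line), "collinear|rank")
})

test_that("plane cuts match closed forms and partition volume", {
  cb <- cube_mesh(10)  # occupies [0,10]^3
  half <- plane_cut(cb, plane(c(0, 0, 1), 5), "below")
  expect_lt(abs(mesh_volume(half) - 500) / 500, 0.001)

  expect_warning(noop <- plane_cut(cb, plane(c(0, 0, 1), -5), "below"),
                 "does not intersect")
  expect_true(isTRUE(attr(noop, "cut_noop")))
  expect_equal(mesh_volume(noop), 1000)

  s <- sphere_mesh(10, subdiv = 4L)
  below <- plane_cut(s, plane(c(0, 0, 1), 5), "below")
  h <- 5; r <- 10
  cap <- pi * h^2 * (3 * r - h) / 3
  expect_lt(abs(mesh_volume(below) - (mesh_volume(s) - cap)) / mesh_volume(s), 0.01)

  # below + above partitions a convex solid
  above <- plane_cut(s, plane(c(0, 0, 1), 5), "above")
  tot <- mesh_volume(s)
  expect_lt(abs(mesh_volume(below) + mesh_volume(above) - tot) / tot, 0.005)

  # tilted plane through a rotated box partitions too
  bx <- make_box(c(1, 2, 3), c(8, 12, 6), rotation = stentforge:::rotation_z(0.4))
  pl <- plane(c(1, 1, 2), 3)
  vb <- mesh_volume(plane_cut(bx, pl, "below"))
  va <- mesh_volume(plane_cut(bx, pl, "above"))
  expect_lt(abs(va + vb - mesh_volume(bx)) / mesh_volume(bx), 0.005)
})

test_that("expanded hull scales exactly and contains its inputs", {
  cb <- cube_mesh(10)
  h0 <- expanded_hull(cb, 0)
  expect_equal(mesh_volume(h0), 1000, tolerance = 1e-9)
  h <- expanded_hull(cb, 0.015)
  expect_lt(abs(mesh_volume(h) - 1000 * 1.015^3) / 1000, 1e-6)

  an <- fx_anatomy("normal")
  hh <- expanded_hull(list(an$maxilla, an$mandible), 0.015)
  expect_true(is_watertight(hh))
  pts <- rbind(an$maxilla$vertices, an$mandible$vertices)
  inside <- points_in_mesh(hh, pts[seq(1, nrow(pts), by = 37), ])
  expect_true(all(inside))

  flat <- tri_mesh(cbind(runif(10), runif(10), 0), matrix(c(1, 2, 3), 1))
  expect_error(expanded_hull(flat), "degenerate|coplanar")
})

test_that("Boolean operations satisfy the algebra of volumes", {
  a <- cube_mesh(10)                      # [0,10]^3
  b <- make_box(c(20, 5, 5), c(10, 10, 10))  # disjoint
  expect_equal(mesh_volume(mesh_boolean(a, b, "union")), 2000, tolerance = 1e-9)
  expect_equal(mesh_volume(mesh_boolean(a, b, "intersect")), 0)

  expect_equal(mesh_volume(mesh_boolean(a, a, "subtract")), 0)

  c5 <- make_box(c(10, 5, 5), c(10, 10, 10))  # 5 mm overlap in x
  un <- mesh_boolean(a, c5, "union")
  it <- mesh_boolean(a, c5, "intersect")
  expect_lt(abs(mesh_volume(un) + mesh_volume(it) -
                  mesh_volume(a) - mesh_volume(c5)) / 2000, 1e-6)
  expect_lt(abs(mesh_volume(un) - voxelize_volume_oracle(un, 256)) /
              mesh_volume(un), 0.01)
  expect_lt(abs(mesh_volume(it) - voxelize_volume_oracle(it, 256)) /
              mesh_volume(it), 0.01)

  open_box <- tri_mesh(a$vertices, a$faces[-1, ])
  expect_error(mesh_boolean(open_box, b, "union"), "watertight")
})

test_that("inclusion-exclusion holds on 50 seeded random cube pairs", {
  set.seed(2024)
  for (k in 1:50) {
    a <- make_box(runif(3, -5, 5), runif(3, 4, 12),
                  rotation = stentforge:::rotation_z(runif(1, 0, pi)))
    b <- make_box(runif(3, -5, 5), runif(3, 4, 12),
                  rotation = stentforge:::rotation_z(runif(1, 0, pi)))
    un <- suppressWarnings(mesh_boolean(a, b, "union"))
    it <- suppressWarnings(mesh_boolean(a, b, "intersect"))
    lhs <- mesh_volume(un, check = FALSE) + mesh_volume(it, check = FALSE)
    rhs <- mesh_volume(a) + mesh_volume(b)
    expect_lt(abs(lhs - rhs) / rhs, 1e-6)
  }
})

test_that("boxes have exact volumes, invariant under rotation", {
  expect_equal(mesh_volume(make_box(c(0, 0, 0), c(10, 10, 10))), 1000)
  expect_equal(mesh_volume(make_box(c(0, 0, 0), c(20, 8, 12))), 1920)
  rot <- make_box(c(0, 0, 0), c(10, 10, 10),
                  rotation = stentforge:::rotation_z(pi / 4))
  expect_equal(mesh_volume(rot), 1000, tolerance = 1e-9)
  expect_error(make_box(extents = c(1, -1, 1)), "positive")
})

test_that("tongue meshes are ellipsoids with the requested volume", {
  unit <- make_tongue_mesh(tongue_params(semi_axes = c(1, 1, 1)))
  expect_lt(abs(mesh_volume(unit) - 4 * pi / 3) / (4 * pi / 3), 0.005)
  abc <- make_tongue_mesh(tongue_params(semi_axes = c(20, 25, 8),
                                        center = c(3, -17, 2)))
  expect_lt(abs(mesh_volume(abc) - 4 * pi * 20 * 25 * 8 / 3) /
              (4 * pi * 20 * 25 * 8 / 3), 0.005)
  expect_error(tongue_params(semi_axes = c(1, 0, 1)), "positive")
})

test_that("protected smoothing freezes protected vertices and preserves volume", {
  gc10 <- gridded_cube(10, 24L)
  # full protection: output identical to input
  same <- smooth_protected(gc10, list(gc10), protect_distance = 0.5,
                           iterations = 10)
  expect_identical(same$vertices, gc10$vertices)

  # unprotected: Taubin keeps the volume within 2 percent
  sm <- smooth_protected(gc10, list(), iterations = 10)
  expect_true(is_watertight(sm))
  expect_lt(abs(mesh_volume(sm, check = FALSE) - mesh_volume(gc10)) /
              mesh_volume(gc10), 0.02)

  expect_error(smooth_protected(gc10, list(), iterations = -1), "non-negative")
})

test_that("the voxel oracle matches analytic volumes", {
  expect_lt(abs(voxelize_volume_oracle(cube_mesh(10), 128) - 1000) / 1000, 0.01)
  expect_equal(voxelize_volume_oracle(empty_mesh(), 64), 0)
  s <- sphere_mesh(10, subdiv = 4L)
  expect_lt(abs(voxelize_volume_oracle(s, 192) - mesh_volume(s)) /
              mesh_volume(s), 0.01)
  expect_error(voxelize_volume_oracle(cube_mesh(), 4), "at least 8")
})
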