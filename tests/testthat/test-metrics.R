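test_that("volume conversion to millilitres", {
  expect_equal(stent_volume_ml(cube_mesh(10)), 1)
  expect_equal(stent_volume_ml(empty_mesh()), 0)
})

test_that("plate thickness on slabs matches closed forms", {
  slab <- make_box(c(0, 0, 5), c(40, 40, 10))  # 10 mm slab, z in [0,10]
  sq <- rbind(c(-10, -10), c(10, -10), c(10, 10), c(-10, 10))
  expect_lt(abs(min_plate_thickness(slab, sq) - 10), 1e-6)

  # 4 mm hemispherical dent in the top face: thinnest point 6 mm
  dent <- mesh_boolean(slab, sphere_mesh(4, center = c(0, 0, 10)), "subtract")
  small <- rbind(c(-3, -3), c(3, -3), c(3, 3), c(-3, 3))
  expect_lt(abs(min_plate_thickness(dent, small, spacing = 0.25) - 6), 0.2)

  # footprint past the silhouette: a missing ray reports zero
  far <- rbind(c(40, 40), c(44, 40), c(44, 44), c(40, 44))
  expect_equal(min_plate_thickness(slab, far), 0)

  expect_error(min_plate_thickness(slab, sq[1:2, ]), "polygon")
})

test_that("thickness shrinks monotonically as the tongue body grows", {
  slab <- make_box(c(0, 0, 6), c(60, 60, 12))
  sq <- rbind(c(-8, -8), c(8, -8), c(8, 8), c(-8, 8))
  prev <- Inf
  for (ax in c(6, 8, 10, 12, 14)) {
    tong <- make_tongue_mesh(tongue_params(semi_axes = c(ax, ax, ax),
                                           center = c(0, 0, 0)))
    carved <- suppressWarnings(mesh_boolean(slab, tong, "subtract"))
    th <- min_plate_thickness(carved, sq, spacing = 0.5)
    expect_lte(th, prev + 1e-9)
    prev <- th
  }
  expect_lt(prev, 12)
})

test_that("plane height fraction anchors at the gum baseline and occlusal extreme", {
  a <- fx_anatomy("normal")
  gb <- a$landmarks["lower_gum_baseline", ]
  zs <- a$mandible$vertices[, 3]
  occ <- zs[which.max(abs(zs - gb[3]))]

  at_gum <- plane(c(0, 0, 1), gb[3])
  expect_equal(plane_height_fraction(at_gum, a$mandible, gb), 0, tolerance = 1e-9)
  at_occ <- plane(c(0, 0, 1), occ)
  expect_equal(plane_height_fraction(at_occ, a$mandible, gb), 1, tolerance = 1e-9)

  expect_error(plane_height_fraction(plane(c(1, 0, 0), 0), a$mandible, gb),
               "vertical")
})

test_that("group comparisons reproduce hand-computed statistics", {
  id <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$mean_difference, 0)
  expect_equal(id$p_value, 1)

  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$mean_difference, -3)
  # Welch t by hand: se = sqrt(1/3 + 1/3), t = -3 / se = -3.6742
  expect_lt(abs(cmp$t - (-3.674)), 1e-3)
  expect_lt(cmp$p_value, 0.05)

  # SEM of {30, 31, 32} is sd/sqrt(n) = 1/sqrt(3) = 0.5774
  s <- design_summary(c(30, 31, 32), "trial")
  expect_lt(abs(s$sem_ml - 0.577), 1e-3)
  expect_equal(s$n, 3L)
  expect_equal(s$sd_ml, 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("comparison is antisymmetric under argument swap", {
  set.seed(9)
  a <- rnorm(6, 30, 2); b <- rnorm(5, 27, 2)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})
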