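test_that("STL round trips preserve topology, bytes and volume", {
  cb <- cube_mesh(10)
  soup <- unweld(cb)

  bin <- withr::local_tempfile(fileext = ".stl")
  write_stl(soup, bin)
  expect_identical(file.size(bin), 84 + 50 * 12)

  back <- read_stl(bin)
  expect_equal(nrow(back$vertices), 8L)   # welded on load
  expect_equal(nrow(back$faces), 12L)
  expect_equal(mesh_volume(back), 1000)

  asc <- withr::local_tempfile(fileext = ".stl")
  write_ascii_stl(soup, asc)
  back_asc <- read_stl(asc)
  expect_equal(sort_rows(back_asc$vertices), sort_rows(back$vertices))
  expect_equal(mesh_volume(back_asc), mesh_volume(back))

  # round trip on a generated mandible: identical signed volume
  md <- fx_anatomy("normal")$mandible
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(md, p)
  md2 <- read_stl(p)
  v0 <- mesh_volume(md)
  expect_lt(abs(mesh_volume(md2) - v0) / v0, 1e-9)
})

test_that("STL errors are informative", {
  expect_error(read_stl(file.path(tempdir(), "no_such.stl")), "not found")
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_stl(empty), "empty|truncated")
  expect_error(write_stl(empty_mesh(), tempfile()), "empty")
  expect_error(write_stl(cube_mesh(), file.path(tempdir(), "nope", "x.stl")),
               "cannot open")
})

test_that("a step checkpoint is parseable by an independent STL reader", {
  md <- fx_anatomy("normal")$mandible
  p <- tempfile(fileext = ".stl")
  write_stl(md, p)
  out <- suppressWarnings(system2("python",
    c("-c", shQuote(sprintf(
      "import trimesh; m = trimesh.load('%s'); print(len(m.faces), m.is_watertight)", p))),
    stdout = TRUE, stderr = TRUE))
  got <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(got[1]), nrow(md$faces))
  expect_equal(got[2], "True")
})

test_that("mesh volume matches closed forms and is rigid-invariant", {
  expect_equal(mesh_volume(cube_mesh(10)), 1000)
  s <- sphere_mesh(10, subdiv = 4L)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.005)

  tr <- rigid_transform(stentforge:::rotation_z(0.7), c(3.2, -1.5, 8))
  v0 <- mesh_volume(s)
  expect_lt(abs(mesh_volume(transform_mesh(s, tr)) - v0) / v0, 1e-9)

  open_box <- tri_mesh(cube_mesh()$vertices, cube_mesh()$faces[-1, ])
  expect_error(mesh_volume(open_box), "watertight")
})

test_that("rigid transforms validate their rotation", {
  expect_error(rigid_transform(diag(3) * 2), "determinant")
  expect_error(rigid_transform(matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3)),
               "determinant")
  tr <- rigid_transform(stentforge:::rotation_z(pi / 4), c(1, 2, 3))
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
})

test_that("repair closes holes and is idempotent", {
  cb <- cube_mesh(10)
  holed <- tri_mesh(cb$vertices, cb$faces[-5, ], "holed")
  expect_false(is_watertight(holed))
  fixed <- repair_watertight(holed, max_boundary_frac = 1)
  expect_true(is_watertight(fixed))
  expect_lt(abs(mesh_volume(fixed) - 1000) / 1000, 0.01)

  # identity on an already-watertight sphere
  s <- sphere_mesh(10)
  s2 <- repair_watertight(s)
  expect_lt(abs(mesh_volume(s2) - mesh_volume(s)) / mesh_volume(s), 1e-9)

  # idempotence
  fixed2 <- repair_watertight(fixed)
  expect_lt(abs(mesh_volume(fixed2) - mesh_volume(fixed)) / mesh_volume(fixed), 1e-9)

  # hopeless inputs are refused
  tri1 <- tri_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
                   matrix(c(1, 2, 3), 1))
  expect_error(repair_watertight(tri1), "irreparable|boundary")
})

test_that("punched scan-artifact holes repair to within half a percent", {
  mx <- fx_anatomy("normal")$maxilla
  v0 <- mesh_volume(mx)
  punched <- punch_holes(mx, holes = 3L, radius = 2, seed = 7)
  expect_false(is_watertight(punched))
  fixed <- repair_watertight(punched)
  expect_true(is_watertight(fixed))
  expect_lt(abs(mesh_volume(fixed) - v0) / v0, 0.005)
})

test_that("welding merges duplicates without moving coordinates", {
  cb <- cube_mesh(10)
  soup <- unweld(cb)
  expect_equal(nrow(soup$vertices), 36L)
  w <- weld_mesh(soup)
  expect_equal(nrow(w$vertices), 8L)
  expect_equal(sort_rows(w$vertices), sort_rows(cb$vertices))
  expect_equal(mesh_volume(w), 1000)
})
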