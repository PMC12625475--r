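tooth_rows <- function(model, arch) {
  nm <- rownames(model$landmarks)
  nm[grepl(paste0("^", arch, "_"), nm) &
       !grepl("ridge_crest|gum_baseline|incisor_tip", nm)]
}

test_that("presets produce the expected dentition and watertight meshes", {
  a <- fx_anatomy("normal")
  expect_length(tooth_rows(a, "upper"), 14L)
  expect_length(tooth_rows(a, "lower"), 14L)
  expect_true(is_watertight(a$maxilla, strict = TRUE))
  expect_true(is_watertight(a$mandible, strict = TRUE))

  e <- fx_anatomy("edentulous")
  expect_length(tooth_rows(e, "upper"), 0L)
  expect_length(tooth_rows(e, "lower"), 0L)
  expect_true(is_watertight(e$mandible, strict = TRUE))

  h <- fx_anatomy("hypodontia")
  expect_lt(length(tooth_rows(h, "upper")) + length(tooth_rows(h, "lower")), 28L)
  expect_gt(length(tooth_rows(h, "lower")), 0L)

  c3 <- fx_anatomy("class3")
  dy <- c3$landmarks["lower_incisor_tip", "y"] - c3$landmarks["upper_incisor_tip", "y"]
  expect_gt(dy, 0)  # mandibular advancement puts the lower tip anterior

  tm <- generate_anatomy("normal", seed = 42,
                         params = anatomy_params(third_molars = TRUE))
  expect_length(grep("lower_third_molar", rownames(tm$landmarks)), 2L)

  expect_error(generate_anatomy("overbite"), "arg")
})

test_that("generation is bit-identical for equal seeds and differs across seeds", {
  a1 <- generate_anatomy("normal", seed = 42)
  a2 <- generate_anatomy("normal", seed = 42)
  expect_identical(a1$maxilla$vertices, a2$maxilla$vertices)
  expect_identical(a1$landmarks, a2$landmarks)
  a3 <- generate_anatomy("normal", seed = 43)
  expect_false(identical(a1$landmarks, a3$landmarks))
})

test_that("the zero-jitter normal arch is mirror symmetric", {
  a <- generate_anatomy("normal", seed = 1, params = anatomy_params(jitter_mm = 0))
  lm <- a$landmarks
  lefts <- grep("_left$", rownames(lm), value = TRUE)
  for (l in lefts) {
    r <- sub("_left$", "_right", l)
    expect_lt(abs(lm[l, "x"] + lm[r, "x"]), 1e-6)
    expect_lt(abs(lm[l, "y"] - lm[r, "y"]), 1e-6)
    expect_lt(abs(lm[l, "z"] - lm[r, "z"]), 1e-6)
  }
})

test_that("landmarks lie on the mesh surface and articulation is exact", {
  for (preset in c("normal", "edentulous", "class3")) {
    a <- fx_anatomy(preset)
    expect_lt(abs(interincisal_distance(a) - 20), 0.5)
    for (arch in c("upper", "lower")) {
      mesh <- if (arch == "upper") a$maxilla else a$mandible
      nms <- grep(paste0("^", arch, "_"), rownames(a$landmarks), value = TRUE)
      near <- stentforge:::.cpp_near_surface(a$landmarks[nms, , drop = FALSE],
                                             mesh$vertices, mesh$faces, 1.0)
      expect_true(all(near), label = paste(preset, arch, "landmarks on surface"))
    }
  }
})

test_that("articulate retargets the opening exactly and path-independently", {
  a <- fx_anatomy("normal")
  a20 <- articulate(a, 20)
  expect_lt(abs(interincisal_distance(a20) - 20), 1e-6)

  a_same <- articulate(a20, interincisal_distance(a20))
  expect_identical(a_same$mandible$vertices, a20$mandible$vertices)

  a_via25 <- articulate(articulate(a, 25), 20)
  expect_equal(a_via25$mandible$vertices, a20$mandible$vertices, tolerance = 1e-12)
  expect_lt(abs(interincisal_distance(a_via25) - 20), 1e-6)
})

test_that("generated meshes pass repair as a no-op", {
  for (preset in c("normal", "edentulous", "hypodontia", "class3")) {
    a <- fx_anatomy(preset)
    r <- repair_watertight(a$mandible)
    expect_lt(abs(mesh_volume(r) - mesh_volume(a$mandible)) /
                mesh_volume(a$mandible), 1e-12)
  }
})

test_that("anatomy round trips through the STL + JSON sidecar files", {
  a <- fx_anatomy("normal")
  dir <- tempfile("anat_")
  write_anatomy(a, dir)
  expect_setequal(list.files(dir),
                  c("maxilla.stl", "mandible.stl", "landmarks.json"))
  back <- read_anatomy(dir)
  expect_equal(back$preset, "normal")
  expect_lt(abs(mesh_volume(back$mandible) - mesh_volume(a$mandible)) /
              mesh_volume(a$mandible), 1e-9)
  expect_equal(back$landmarks[rownames(a$landmarks), ], a$landmarks,
               tolerance = 1e-12)
})
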