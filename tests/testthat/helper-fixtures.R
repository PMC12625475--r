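# Shared fixtures, built in code and cached for the session: full pipeline
# runs are expensive, and several files inspect the same seed-42 design.

.fx <- new.env(parent = emptyenv())

fx_anatomy <- function(preset = "normal", seed = 42, ...) {
  key <- paste("anat", preset, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_anatomy(preset, seed = seed,
                                   params = anatomy_params(...))
  .fx[[key]]
}

# cached full pipeline run (suppresses the multi-component note)
fx_design <- function(preset = "normal", seed = 42, ...) {
  key <- paste("run", preset, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- suppressMessages(suppressWarnings(
      design_stent(fx_anatomy(preset, seed, ...))))
  .fx[[key]]
}

# an independent repeat of the seed-42 normal design, for determinism checks
fx_design_repeat <- function() {
  if (is.null(.fx[["repeat"]]))
    .fx[["repeat"]] <- suppressMessages(suppressWarnings(
      design_stent(fx_anatomy("normal"))))
  .fx[["repeat"]]
}

cube_mesh <- function(side = 10, center = c(side / 2, side / 2, side / 2)) {
  make_box(center = center, extents = rep(side, 3))
}

sphere_mesh <- function(radius = 10, center = c(0, 0, 0), subdiv = 4L) {
  s <- stentforge:::icosphere(subdiv)
  s$vertices <- sweep(s$vertices * radius, 2L, center, "+")
  s
}

# a cube tessellated on a fine grid (n cells per axis), watertight
gridded_cube <- function(side = 10, n = 24L) {
  occ <- rep(TRUE, n^3)
  s <- stentforge:::.cpp_voxel_surface(occ, n, n, n, 0, 0, 0, side / n)
  tri_mesh(s$vertices, s$faces, "gridded_cube")
}

# duplicate every vertex per face (STL-style soup) to exercise welding
unweld <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices[as.vector(t(f)), , drop = FALSE]
  tri_mesh(v, matrix(seq_len(3 * nrow(f)), ncol = 3, byrow = TRUE),
           mesh$provenance)
}

# punch approximately `holes` holes of the given radius into a mesh by
# deleting the faces within the radius of seeded surface vertices
punch_holes <- function(mesh, holes = 3L, radius = 2, seed = 7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- mesh$vertices[sample(nrow(mesh$vertices), holes), , drop = FALSE]
  fc <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
           mesh$vertices[mesh$faces[, 3], ]) / 3
  drop <- rep(FALSE, nrow(mesh$faces))
  for (i in seq_len(holes)) {
    d2 <- rowSums(sweep(fc, 2L, centers[i, ])^2)
    drop <- drop | d2 < radius^2
  }
  tri_mesh(mesh$vertices, mesh$faces[!drop, , drop = FALSE], mesh$provenance)
}

# write an ASCII STL (the package itself only writes binary)
write_ascii_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid ascii", con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    writeLines(c("facet normal 0 0 0", "outer loop",
                 sprintf("vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "endloop", "endfacet"), con)
  }
  writeLines("endsolid ascii", con)
  path
}

# centroid (mm) of the lower tooth landmarks, as used by the auto-placement
lower_tooth_centroid <- function(anatomy) {
  lm <- anatomy$landmarks
  tooth <- grepl("^lower_", rownames(lm)) &
    !grepl("ridge_crest|gum_baseline|incisor_tip", rownames(lm))
  colMeans(lm[tooth, , drop = FALSE])
}

sort_rows <- function(m) {
  m <- unname(as.matrix(m))
  m[do.call(order, as.data.frame(m)), ]
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
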