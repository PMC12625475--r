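#' Triangle mesh constructor
#'
#' The package's basic geometric object: an indexed triangle surface in
#' millimetres. All pipeline inputs, intermediates and outputs are
#' `tri_mesh` objects. A mesh intended for volume queries or Boolean
#' operations must be watertight (closed, consistently outward-oriented);
#' see [repair_watertight()] and [is_watertight()].
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param provenance free-text label recording which step produced the mesh.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, provenance = "") {
  vertices <- as.matrix(vertices)
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1] < 1L || rng[2] > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
  }
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)[1]),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (nzchar(x$provenance)) cat(sprintf(" [%s]", x$provenance))
  cat("\n")
  if (nrow(x$faces) > 0L) {
    bb <- apply(x$vertices, 2L, range)
    cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

empty_mesh <- function(provenance = "empty") {
  tri_mesh(matrix(numeric(0), 0L, 3L), matrix(integer(0), 0L, 3L), provenance)
}

is_empty_mesh <- function(mesh) nrow(mesh$faces) == 0L

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) stop("expected a tri_mesh object")
  invisible(mesh)
}

mesh_bbox <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) return(matrix(0, 2L, 3L))
  apply(mesh$vertices, 2L, range)
}

bbox_diag <- function(mesh) {
  bb <- mesh_bbox(mesh)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

#' Signed-tetrahedron mesh volume
#'
#' Volume by the divergence theorem: the sum of signed tetrahedra spanned by
#' the origin and each face. Exact for watertight, consistently oriented
#' meshes (positive for outward orientation) and invariant under rigid
#' motion.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param check verify watertightness first (default `TRUE`).
#' @return Volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  stopifnot_mesh(mesh)
  if (is_empty_mesh(mesh)) return(0)
  if (check && !is_watertight(mesh))
    stop("mesh is not watertight; run repair_watertight() first")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

# solid (volume) centroid by the divergence theorem
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det) / 6
  if (abs(vol) < 1e-12) return(colMeans(v))
  colSums(det * (a + b + c_) / 24) / vol
}

#' Watertightness test
#'
#' A mesh is watertight when every edge is traversed equally often in both
#' directions (closed, orientation-consistent boundary). With
#' `strict = TRUE` the surface must additionally be 2-manifold (every edge
#' shared by exactly two faces).
#'
#' @param mesh a [tri_mesh()].
#' @param strict also require 2-manifoldness.
#' @export
is_watertight <- function(mesh, strict = FALSE) {
  stopifnot_mesh(mesh)
  if (is_empty_mesh(mesh)) return(TRUE)
  st <- .cpp_edge_status(nrow(mesh$vertices), mesh$faces)
  ok <- st$n_unbalanced == 0
  if (strict) ok <- ok && st$n_nonmanifold == 0
  ok
}

#' Merge coincident vertices and drop degenerate triangles
#'
#' STL stores three independent vertices per triangle; welding restores the
#' shared-vertex topology. Vertices are merged when equal after rounding to
#' `tol` (default 1e-6 mm); coordinates are never moved.
#'
#' @param mesh a [tri_mesh()].
#' @param tol merge tolerance in mm.
#' @export
weld_mesh <- function(mesh, tol = 1e-6) {
  stopifnot_mesh(mesh)
  if (is_empty_mesh(mesh)) return(mesh)
  r <- .cpp_weld(mesh$vertices, mesh$faces, tol)
  tri_mesh(r$vertices, r$faces, mesh$provenance)
}

#' Rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant must be +1 (got ", format(det(rotation)), ")")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot_mesh(mesh)
  if (!inherits(transform, "rigid_transform")) stop("expected a rigid_transform")
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2L, transform$translation, "+")
  tri_mesh(v, mesh$faces, mesh$provenance)
}

# rotation about z axis, radians
rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Read an STL file
#'
#' Reads binary or ASCII stereolithography files; the dialect is detected
#' automatically. Vertices are welded by exact coordinate match (1e-6 mm
#' rounding). STL carries no units; coordinates are taken as millimetres.
#'
#' @param path file path.
#' @param provenance optional provenance label (defaults to the file name).
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not a readable STL file (empty or truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 84L))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (ntri == 0L) stop("STL file contains no triangles: ", path)
    raw <- readBin(con, "raw", n = 50 * ntri)
    # each record: 12 floats (48 bytes) + uint16 attribute
    idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(seq_len(48L), ntri)
    fl <- readBin(raw[idx], "numeric", size = 4L, n = 12L * ntri, endian = "little")
    m <- matrix(fl, ncol = 12L, byrow = TRUE)
    verts <- matrix(0, 3L * ntri, 3L)
    verts[seq(1L, 3L * ntri, by = 3L), ] <- m[, 4:6, drop = FALSE]
    verts[seq(2L, 3L * ntri, by = 3L), ] <- m[, 7:9, drop = FALSE]
    verts[seq(3L, 3L * ntri, by = 3L), ] <- m[, 10:12, drop = FALSE]
    faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
    mesh <- tri_mesh(verts, faces, provenance)
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("cannot parse STL file (not binary, not valid ASCII): ", path)
    nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                     function(s) as.numeric(s[2:4]), numeric(3)))
    if (anyNA(nums)) stop("cannot parse ASCII STL vertex coordinates: ", path)
    ntri <- nrow(nums) / 3L
    faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
    mesh <- tri_mesh(nums, faces, provenance)
  }
  # STL repeats each shared vertex as an exact copy: dedup by exact match
  weld_mesh(mesh, tol = 1e-9)
}

#' Write a binary STL file
#'
#' @param mesh a non-empty [tri_mesh()].
#' @param path output path. The file is always binary STL
#'   (84 + 50 x nfaces bytes).
#' @export
write_stl <- function(mesh, path) {
  stopifnot_mesh(mesh)
  if (is_empty_mesh(mesh)) stop("refusing to write an empty mesh to ", path)
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "stentforge binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  rec <- matrix(0, nf, 12L)
  rec[, 1:3] <- n; rec[, 4:6] <- a; rec[, 7:9] <- b; rec[, 10:12] <- c_
  flat <- as.numeric(t(rec))
  # each 50-byte record: 48 bytes of floats + 2 zero attribute bytes
  fl_raw <- writeBin(flat, raw(), size = 4L, endian = "little")
  out <- raw(50L * nf)
  tgt <- rep((seq_len(nf) - 1L) * 50L, each = 48L) + rep(1:48, nf)
  out[tgt] <- fl_raw
  writeBin(out, con)
  invisible(path)
}

#' Repair a mesh to watertightness
#'
#' Mirrors the post-processing applied to intraoral scans: weld duplicated
#' vertices, drop degenerate/overlapping triangles, fill boundary-loop holes
#' (ear clipping against each loop's best-fit plane), and restore a
#' consistent outward orientation (total signed volume positive). Idempotent
#' on already-watertight meshes.
#'
#' @param mesh a [tri_mesh()].
#' @param max_boundary_frac refuse inputs whose boundary-edge fraction
#'   exceeds this (default 0.05): such meshes are scan failures, not
#'   hole-punched surfaces.
#' @return A watertight [tri_mesh()].
#' @export
repair_watertight <- function(mesh, max_boundary_frac = 0.05) {
  stopifnot_mesh(mesh)
  if (is_empty_mesh(mesh)) stop("cannot repair an empty mesh")
  m <- weld_mesh(mesh)
  st <- .cpp_edge_status(nrow(m$vertices), m$faces)
  if (st$n_unbalanced / max(st$n_edges, 1) > max_boundary_frac)
    stop(sprintf(paste0("mesh looks irreparable: %.1f%% boundary edges ",
                        "(limit %.1f%%)"),
         100 * st$n_unbalanced / max(st$n_edges, 1), 100 * max_boundary_frac))
  if (st$n_unbalanced > 0) {
    loops <- .cpp_boundary_loops(nrow(m$vertices), m$faces)
    newf <- lapply(loops, function(loop) fill_loop(m$vertices, loop))
    if (length(newf)) m <- tri_mesh(m$vertices, rbind(m$faces, do.call(rbind, newf)),
                                    m$provenance)
  }
  o <- .cpp_orient(m$vertices, m$faces)
  m <- tri_mesh(m$vertices, o$faces, m$provenance)
  if (!is_watertight(m))
    stop("repair failed: mesh still has open boundary after hole filling")
  if (mesh_volume(m, check = FALSE) <= 0)
    stop("repair failed: enclosed volume is not positive")
  m
}

# Triangulate one boundary loop (1-based vertex indices, given in boundary
# halfedge direction) by ear clipping in the loop's best-fit plane; falls
# back to a fan if clipping stalls. Emitted triangles traverse the loop
# backwards, so each boundary halfedge gains its missing partner.
fill_loop <- function(vertices, loop) {
  pts <- vertices[loop, , drop = FALSE]
  n <- length(loop)
  if (n == 3L) return(matrix(loop[c(1L, 3L, 2L)], 1L, 3L))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  basis <- sv$v[, 1:2, drop = FALSE]
  p2 <- sweep(pts, 2L, ctr) %*% basis
  # ensure counter-clockwise in 2D
  area2 <- sum(p2[, 1] * p2[c(2:n, 1L), 2] - p2[c(2:n, 1L), 1] * p2[, 2])
  idx <- seq_len(n)
  reversed <- area2 < 0
  if (reversed) { idx <- rev(idx); p2 <- p2[idx, , drop = FALSE] }
  active <- seq_len(n)
  tris <- list()
  guard <- 0L
  while (length(active) > 3L && guard < n * n) {
    guard <- guard + 1L
    m <- length(active)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- active[if (k == 1L) m else k - 1L]
      i1 <- active[k]
      i2 <- active[if (k == m) 1L else k + 1L]
      a <- p2[i0, ]; b <- p2[i1, ]; cc <- p2[i2, ]
      cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
      if (cr <= 1e-12) next # reflex or degenerate corner
      others <- setdiff(active, c(i0, i1, i2))
      if (length(others)) {
        q <- p2[others, , drop = FALSE]
        d1 <- (b[1] - a[1]) * (q[, 2] - a[2]) - (b[2] - a[2]) * (q[, 1] - a[1])
        d2 <- (cc[1] - b[1]) * (q[, 2] - b[2]) - (cc[2] - b[2]) * (q[, 1] - b[1])
        d3 <- (a[1] - cc[1]) * (q[, 2] - cc[2]) - (a[2] - cc[2]) * (q[, 1] - cc[1])
        if (any(d1 > 0 & d2 > 0 & d3 > 0)) next
      }
      tris[[length(tris) + 1L]] <- loop[idx[c(i0, i1, i2)]]
      active <- setdiff(active, i1)
      clipped <- TRUE
      break
    }
    if (!clipped) break
  }
  if (length(active) == 3L) {
    tris[[length(tris) + 1L]] <- loop[idx[active]]
    out <- do.call(rbind, tris)
  } else {
    # stalled: fan over whatever remains (robust, possibly uglier)
    fan <- cbind(loop[idx[active[1L]]],
                 loop[idx[active[2:(length(active) - 1L)]]],
                 loop[idx[active[3:length(active)]]])
    out <- rbind(if (length(tris)) do.call(rbind, tris), fan)
  }
  # triangles currently traverse the working (CCW) order; make them
  # anti-loop so boundary halfedges get their missing partners
  if (!reversed) out <- out[, c(1L, 3L, 2L), drop = FALSE]
  out
}
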