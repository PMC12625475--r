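#' Oriented plane
#'
#' Hessian normal form: points `p` with `dot(normal, p) == offset` lie on the
#' plane. The normal is normalised to unit length on construction.
#'
#' @param normal length-3 direction (need not be unit length).
#' @param offset signed distance term in mm.
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  l <- sqrt(sum(normal^2))
  if (l < 1e-12) stop("plane normal must be non-zero")
  structure(list(normal = normal / l, offset = as.numeric(offset) / l),
            class = "stent_plane")
}

#' @export
print.stent_plane <- function(x, ...) {
  cat(sprintf("<plane> normal (%.4f, %.4f, %.4f), offset %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

# signed distances of points to a plane
plane_distance <- function(pl, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  as.vector(points %*% pl$normal) - pl$offset
}

#' Best-fit plane by principal component analysis
#'
#' The plane through the centroid whose normal is the direction of least
#' variance (smallest singular vector of the centred point cloud). Used to
#' derive the occlusal planes of each dental arch. The normal sign is chosen
#' to have a positive component along the occlusal (+Z) axis.
#'
#' @param points n x 3 matrix, n >= 3, not all collinear.
#' @return A [plane()].
#' @export
fit_plane_pca <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr))
  scale_ref <- max(sv$d[1], 1e-12)
  if (sv$d[2] / scale_ref < 1e-9)
    stop("points are collinear or coincident: plane fit is rank deficient")
  n <- sv$v[, 3L]
  if (n[3] < 0 || (n[3] == 0 && (n[1] < 0 || (n[1] == 0 && n[2] < 0)))) n <- -n
  plane(n, sum(n * ctr))
}

# orthonormal frame (u, v, n) from a unit normal
plane_frame <- function(n) {
  ref <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
         else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- c(n[2] * ref[3] - n[3] * ref[2],
         n[3] * ref[1] - n[1] * ref[3],
         n[1] * ref[2] - n[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v, n = n)
}

#' Cut a mesh with a plane
#'
#' Executed as a Boolean subtraction between the mesh and a large cuboid with
#' one face coincident with the plane, lying on the discarded side; the cut
#' cross-section is therefore capped and the result watertight. If the plane
#' misses the mesh entirely the input is returned unchanged with a warning
#' (and attribute `cut_noop = TRUE`).
#'
#' @param mesh a watertight [tri_mesh()].
#' @param cut_plane a [plane()].
#' @param keep which side to keep: `"below"` (`dot(n, p) <= offset`) or
#'   `"above"`.
#' @export
plane_cut <- function(mesh, cut_plane, keep = c("below", "above")) {
  stopifnot_mesh(mesh)
  keep <- match.arg(keep)
  if (is_empty_mesh(mesh)) return(mesh)
  d <- plane_distance(cut_plane, mesh$vertices)
  keep_sign <- if (keep == "below") -1 else 1
  if (all(d >= -1e-9) || all(d <= 1e-9)) {
    # the plane misses the mesh: nothing to cut, whichever side is kept
    warning("plane does not intersect the mesh; returning input unchanged")
    attr(mesh, "cut_noop") <- TRUE
    return(mesh)
  }
  L <- 10 * bbox_diag(mesh)
  fr <- plane_frame(cut_plane$normal)
  ctr_on_plane <- mesh_centroid(mesh) -
    plane_distance(cut_plane, matrix(mesh_centroid(mesh), 1L)) * cut_plane$normal
  box_center <- ctr_on_plane - keep_sign * cut_plane$normal * (L / 2)
  rot <- cbind(fr$u, fr$v, fr$n)
  box <- make_box(box_center, c(L, L, L), rotation = rot)
  out <- mesh_boolean(mesh, box, "subtract")
  out$provenance <- paste0(mesh$provenance, "|cut")
  out
}

#' Expanded convex hull of one or more meshes
#'
#' The combined convex hull of all vertices, expanded outward by
#' `expand_fraction`. The default mode scales the hull uniformly by
#' `(1 + expand_fraction)` about its volume centroid, so hull volume grows
#' exactly by `(1 + f)^3`; `"normal_offset"` instead displaces each hull
#' vertex along its angle-averaged outward normal by `f` times its distance
#' to the centroid.
#'
#' @param meshes a [tri_mesh()] or list of them.
#' @param expand_fraction unitless outward expansion (default 0.015, i.e.
#'   1.5 percent).
#' @param mode `"isotropic"` (default) or `"normal_offset"`.
#' @return A convex watertight [tri_mesh()].
#' @export
expanded_hull <- function(meshes, expand_fraction = 0.015,
                          mode = c("isotropic", "normal_offset")) {
  mode <- match.arg(mode)
  if (inherits(meshes, "tri_mesh")) meshes <- list(meshes)
  pts <- do.call(rbind, lapply(meshes, function(m) {
    stopifnot_mesh(m); m$vertices
  }))
  if (is.null(pts) || nrow(pts) < 4L) stop("need at least 4 points for a 3D hull")
  faces <- tryCatch(.cpp_convex_hull(pts),
                    error = function(e) stop("degenerate hull: ", conditionMessage(e)))
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  hull <- tri_mesh(pts[used, , drop = FALSE],
                   matrix(remap[faces], ncol = 3L), "convex_hull")
  hull <- weld_mesh(hull)
  if (expand_fraction != 0) {
    ctr <- mesh_centroid(hull)
    if (mode == "isotropic") {
      hull$vertices <- sweep(sweep(hull$vertices, 2L, ctr) * (1 + expand_fraction),
                             2L, ctr, "+")
    } else {
      vn <- vertex_normals(hull)
      r <- sqrt(rowSums(sweep(hull$vertices, 2L, ctr)^2))
      hull$vertices <- hull$vertices + vn * (expand_fraction * r)
    }
  }
  hull$provenance <- "expanded_hull"
  hull
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate_weighted(f[, k], fn[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate_weighted(f[, k], fn[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate_weighted(f[, k], fn[, 3], nrow(v))
  }
  l <- sqrt(rowSums(vn^2))
  l[l == 0] <- 1
  vn / l
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Boolean operation between two watertight meshes
#'
#' Constructive solid geometry via a BSP-tree algorithm (both operands are
#' compiled to binary space partition trees and clipped against each other;
#' coplanar faces are routed by normal agreement). The raw result is welded,
#' T-junctions along the intersection curve are stitched, and the output is
#' verified closed. If verification fails the operation falls back to voxel
#' remeshing at 256 voxels along the longest axis, with a warning: Boolean
#' robustness is treated as a first-class requirement, and an approximate
#' watertight answer beats an exact broken one.
#'
#' @param a,b watertight [tri_mesh()] operands.
#' @param op `"union"`, `"subtract"` or `"intersect"`.
#' @param fallback_resolution voxels along the longest axis for the fallback
#'   remesh.
#' @return A watertight [tri_mesh()] (possibly empty).
#' @export
mesh_boolean <- function(a, b, op = c("union", "subtract", "intersect"),
                         fallback_resolution = 256L) {
  op <- match.arg(op)
  stopifnot_mesh(a); stopifnot_mesh(b)
  if (!is_empty_mesh(a) && !is_watertight(a))
    stop("operand A is not watertight; run repair_watertight() first")
  if (!is_empty_mesh(b) && !is_watertight(b))
    stop("operand B is not watertight; run repair_watertight() first")
  if (is_empty_mesh(a))
    return(switch(op, union = b, subtract = empty_mesh(), intersect = empty_mesh()))
  if (is_empty_mesh(b))
    return(switch(op, union = a, subtract = a, intersect = empty_mesh()))
  # disjoint bounding boxes: the answer needs no clipping at all
  ba <- mesh_bbox(a); bb <- mesh_bbox(b)
  if (any(ba[1, ] > bb[2, ] + 1e-12) || any(bb[1, ] > ba[2, ] + 1e-12)) {
    return(switch(op,
                  union = concat_meshes(a, b),
                  subtract = a,
                  intersect = empty_mesh()))
  }
  raw <- .cpp_csg(a$vertices, a$faces, b$vertices, b$faces, op)
  out <- clean_csg_output(raw, paste0(op, "(", a$provenance, ",", b$provenance, ")"))
  if (!is.null(out)) return(out)
  warning(sprintf("BSP %s produced a non-closed surface; falling back to voxel remeshing",
                  op))
  voxel_boolean(a, b, op, fallback_resolution)
}

# weld -> stitch T-junctions -> weld -> patch residual micro-cracks;
# NULL if the surface still is not closed
clean_csg_output <- function(raw, provenance, weld_tol = 1e-6) {
  if (nrow(raw$faces) == 0L) return(empty_mesh(provenance))
  m <- .cpp_weld(raw$vertices, raw$faces, weld_tol, area2_tol = 1e-14)
  for (round in 1:3) {
    if (nrow(m$faces) == 0L) return(empty_mesh(provenance))
    st <- .cpp_edge_status(nrow(m$vertices), m$faces)
    if (st$n_unbalanced == 0) break
    m <- .cpp_stitch_tjunctions(m$vertices, m$faces, 1e-5)
    m <- .cpp_weld(m$vertices, m$faces, weld_tol)
    if (nrow(m$faces) == 0L) return(empty_mesh(provenance))
    st <- .cpp_edge_status(nrow(m$vertices), m$faces)
    if (st$n_unbalanced > 0 && st$n_unbalanced <= 5000) {
      # residual hairline cracks: close them like scan holes
      loops <- .cpp_boundary_loops(nrow(m$vertices), m$faces)
      if (length(loops)) {
        newf <- lapply(loops, function(loop) fill_loop(m$vertices, loop))
        m$faces <- rbind(m$faces, do.call(rbind, newf))
      }
    }
  }
  mesh <- tri_mesh(m$vertices, m$faces, provenance)
  if (!is_watertight(mesh)) return(NULL)
  if (abs(mesh_volume(mesh, check = FALSE)) < 1e-9) return(empty_mesh(provenance))
  mesh
}

# two disjoint closed shells as one mesh
concat_meshes <- function(a, b) {
  if (is_empty_mesh(a)) return(b)
  if (is_empty_mesh(b)) return(a)
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)),
           paste0(a$provenance, "+", b$provenance))
}

# voxel-remesh fallback for Boolean ops; the grid only needs to cover the
# region the result can occupy (A for subtraction, the bbox overlap for
# intersection), which keeps the pitch fine even against huge cutters
voxel_boolean <- function(a, b, op, resolution = 256L) {
  ba <- mesh_bbox(a); bb <- mesh_bbox(b)
  if (op == "union") {
    lo <- pmin(ba[1, ], bb[1, ]); hi <- pmax(ba[2, ], bb[2, ])
  } else if (op == "subtract") {
    lo <- ba[1, ]; hi <- ba[2, ]
  } else {
    lo <- pmax(ba[1, ], bb[1, ]); hi <- pmin(ba[2, ], bb[2, ])
    if (any(lo >= hi)) return(empty_mesh())
  }
  pitch <- max(hi - lo) / resolution
  lo <- lo - 2 * pitch
  n <- pmin(ceiling((hi + 2 * pitch - lo) / pitch), resolution + 4L)
  occa <- .cpp_occupancy(a$vertices, a$faces, lo[1], lo[2], lo[3], pitch,
                         n[1], n[2], n[3])
  occb <- .cpp_occupancy(b$vertices, b$faces, lo[1], lo[2], lo[3], pitch,
                         n[1], n[2], n[3])
  occ <- switch(op, union = occa | occb, subtract = occa & !occb,
                intersect = occa & occb)
  if (!any(occ)) return(empty_mesh())
  s <- .cpp_voxel_surface(occ, n[1], n[2], n[3], lo[1], lo[2], lo[3], pitch)
  tri_mesh(s$vertices, s$faces, paste0("voxel_", op))
}

#' Axis-aligned or rotated cuboid
#'
#' @param center length-3 centre (mm).
#' @param extents length-3 full edge lengths (mm), all positive.
#' @param rotation optional 3 x 3 rotation applied about the centre.
#' @return A watertight 12-triangle [tri_mesh()].
#' @export
make_box <- function(center = c(0, 0, 0), extents = c(1, 1, 1), rotation = NULL) {
  extents <- as.numeric(extents)
  if (any(extents <= 0)) stop("box extents must be positive")
  h <- extents / 2
  corn <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  v <- sweep(corn, 2L, h, "*")
  if (!is.null(rotation)) v <- v %*% t(rotation)
  v <- sweep(v, 2L, as.numeric(center), "+")
  # outward-wound faces of the cube in expand.grid vertex order (x fastest)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # bottom (-z)
             c(5, 6, 8), c(5, 8, 7),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(3, 7, 8), c(3, 8, 4),   # back (+y)
             c(1, 5, 7), c(1, 7, 3),   # left (-x)
             c(2, 4, 8), c(2, 8, 6))   # right (+x)
  m <- tri_mesh(v, f, "box")
  if (mesh_volume(m, check = FALSE) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Tongue-space parameters
#'
#' The tongue-like body subtracted from the lower stent is an ellipsoid whose
#' semi-axes and pose are fully adjustable.
#'
#' @param semi_axes three positive semi-axis lengths (mm): lateral,
#'   anteroposterior, vertical.
#' @param center ellipsoid centre (mm).
#' @param orientation 3 x 3 rotation.
#' @param posterior_offset default posterior translation (mm) applied by the
#'   pipeline's auto-placement (17.5 mm, so the tongue tip sits behind the
#'   incisors).
#' @export
tongue_params <- function(semi_axes = c(20, 25, 8), center = c(0, 0, 0),
                          orientation = diag(3), posterior_offset = 17.5) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be 3 positive lengths")
  structure(list(semi_axes = semi_axes, center = as.numeric(center),
                 orientation = as.matrix(orientation),
                 posterior_offset = as.numeric(posterior_offset)),
            class = "tongue_params")
}

#' Ellipsoidal tongue mesh
#'
#' Icosphere (subdivision level 4, 5120 faces, volume within 0.25 percent
#' of the exact ellipsoid) scaled by the semi-axes, rotated and centred.
#'
#' @param params a [tongue_params()].
#' @export
make_tongue_mesh <- function(params = tongue_params()) {
  if (!inherits(params, "tongue_params")) stop("expected tongue_params")
  s <- icosphere(4L)
  v <- sweep(s$vertices, 2L, params$semi_axes, "*")
  v <- v %*% t(params$orientation)
  v <- sweep(v, 2L, params$center, "+")
  tri_mesh(v, s$faces, "tongue")
}

# unit icosphere by repeated midpoint subdivision of an icosahedron
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      assign(key, idx, envir = mid_cache)
      idx
    }
    nf <- matrix(0L, 0L, 3L)
    ff <- matrix(0L, nrow(f) * 4L, 3L)
    r <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      ff[r + 1L, ] <- c(a, ab, ca)
      ff[r + 2L, ] <- c(b, bc, ab)
      ff[r + 3L, ] <- c(cc, ca, bc)
      ff[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- ff
  }
  m <- tri_mesh(v, f, "icosphere")
  if (mesh_volume(m, check = FALSE) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Feature-protected Taubin smoothing
#'
#' Taubin lambda/mu smoothing (volume-preserving pair of Laplacian steps)
#' applied only to vertices farther than `protect_distance` from every
#' protected surface. Vertices within the protection band are bit-identical
#' in the output: this is how the dental impression survives the final
#' smoothing pass.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param protected_surfaces list of [tri_mesh()] whose vicinity must not
#'   move (may be empty).
#' @param protect_distance protection band in mm (default 0.5).
#' @param iterations smoothing iterations (default 10).
#' @param lambda,mu Taubin shrink/inflate factors (defaults 0.5, -0.53).
#' @export
smooth_protected <- function(mesh, protected_surfaces = list(),
                             protect_distance = 0.5, iterations = 10L,
                             lambda = 0.5, mu = -0.53) {
  stopifnot_mesh(mesh)
  if (iterations < 0) stop("iterations must be non-negative")
  if (is_empty_mesh(mesh) || iterations == 0L) return(mesh)
  if (inherits(protected_surfaces, "tri_mesh"))
    protected_surfaces <- list(protected_surfaces)
  movable <- rep(TRUE, nrow(mesh$vertices))
  for (ps in protected_surfaces) {
    stopifnot_mesh(ps)
    if (is_empty_mesh(ps)) next
    near <- .cpp_near_surface(mesh$vertices, ps$vertices, ps$faces, protect_distance)
    movable <- movable & !near
  }
  v <- .cpp_taubin(mesh$vertices, mesh$faces, movable, lambda, mu, as.integer(iterations))
  tri_mesh(v, mesh$faces, paste0(mesh$provenance, "|smoothed"))
}

#' Point-in-solid test
#'
#' Classifies points against a watertight mesh by vertical-ray winding.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param points n x 3 matrix of query points (mm).
#' @return Logical vector: `TRUE` for points strictly inside.
#' @export
points_in_mesh <- function(mesh, points) {
  stopifnot_mesh(mesh)
  points <- matrix(as.numeric(points), ncol = 3L)
  if (is_empty_mesh(mesh)) return(rep(FALSE, nrow(points)))
  .cpp_points_inside(mesh$vertices, mesh$faces, points)
}

#' Voxel volume oracle
#'
#' Independent volume estimate used to cross-check Boolean and cut results:
#' vertical parity rays on a `resolution^2` grid of columns, with exact
#' integration of the inside intervals along z. Deliberately shares no code
#' path with [mesh_volume()].
#'
#' @param mesh a watertight [tri_mesh()].
#' @param resolution columns per axis (>= 8).
#' @return Volume in cubic millimetres.
#' @export
voxelize_volume_oracle <- function(mesh, resolution = 192L) {
  stopifnot_mesh(mesh)
  if (resolution < 8) stop("resolution must be at least 8")
  if (is_empty_mesh(mesh)) return(0)
  if (!is_watertight(mesh)) stop("voxel oracle requires a watertight mesh")
  bb <- mesh_bbox(mesh)
  pitch <- max(bb[2, ] - bb[1, ]) / resolution
  lo <- bb[1, ] - pitch
  n <- ceiling((bb[2, ] + pitch - lo) / pitch)
  .cpp_column_volume(mesh$vertices, mesh$faces, lo[1], lo[2], pitch, n[1], n[2])
}
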