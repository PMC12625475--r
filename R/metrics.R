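#' Stent volume in millilitres
#'
#' @param mesh a watertight [tri_mesh()].
#' @return Volume in mL (1 mL = 1000 mm^3).
#' @export
stent_volume_ml <- function(mesh) {
  mesh_volume(mesh) / 1000
}

#' Minimum plate thickness under a footprint
#'
#' Minimum inside-length of vertical rays cast through the stent over a
#' regular grid of points inside `footprint` (a planar polygon in the XY
#' plane). Rays that miss the stent entirely yield 0, so a footprint
#' reaching past the stent silhouette reports zero thickness. Thickness is
#' measured along the occlusal (Z) axis.
#'
#' @param stent a watertight [tri_mesh()].
#' @param footprint polygon as an n x 2 matrix of XY vertices (mm), n >= 3.
#' @param spacing grid spacing in mm (default 0.5).
#' @return Minimum thickness in mm.
#' @export
min_plate_thickness <- function(stent, footprint, spacing = 0.5) {
  stopifnot_mesh(stent)
  if (!is_watertight(stent)) stop("stent must be watertight")
  footprint <- as.matrix(footprint)
  if (nrow(footprint) < 3L || ncol(footprint) != 2L)
    stop("footprint must be an n x 2 polygon with n >= 3")
  xr <- range(footprint[, 1]); yr <- range(footprint[, 2])
  gx <- seq(xr[1], xr[2], by = spacing)
  gy <- seq(yr[1], yr[2], by = spacing)
  g <- expand.grid(x = gx, y = gy)
  keep <- points_in_polygon(g$x, g$y, footprint)
  if (!any(keep)) stop("footprint polygon contains no grid points at this spacing")
  # tiny deterministic shear so rays never pass exactly through mesh edges
  lens <- .cpp_ray_inside_lengths(stent$vertices, stent$faces,
                                  g$x[keep] + spacing * 1.2e-3,
                                  g$y[keep] + spacing * 2.7e-3)
  min(lens)
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# clip a convex/simple polygon by the half-plane a*x + b*y <= c
clip_polygon_halfplane <- function(poly, a, b, c_) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c_
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 0) out[[length(out) + 1L]] <- poly[i, ]
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      out[[length(out) + 1L]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (length(out) < 3L) return(poly[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Height fraction of a plane within an arch
#'
#' Where a cutting plane sits along an arch's occlusal height: 0 at the gum
#' baseline, 1 at the occlusal extreme (the arch vertex farthest from the
#' baseline along Z). Used to verify the 60 %/40 % occlusal-plane placement
#' rule on actual geometry.
#'
#' @param cut_plane a [plane()].
#' @param arch the arch [tri_mesh()].
#' @param gum_baseline length-3 gum baseline landmark (mm).
#' @export
plane_height_fraction <- function(cut_plane, arch, gum_baseline) {
  stopifnot_mesh(arch)
  gz <- unname(gum_baseline[3])
  zs <- arch$vertices[, 3]
  occ <- zs[which.max(abs(zs - gz))]
  if (abs(occ - gz) < 1e-9) stop("arch has zero occlusal extent above the gum baseline")
  ctr <- colMeans(arch$vertices)
  nz <- cut_plane$normal[3]
  if (abs(nz) < 1e-9) stop("plane is vertical: no defined height fraction")
  plane_z <- (cut_plane$offset - cut_plane$normal[1] * ctr[1] -
                cut_plane$normal[2] * ctr[2]) / nz
  (plane_z - gz) / (occ - gz)
}

#' Descriptive summary of a set of stent volumes
#'
#' @param volumes_ml numeric vector of volumes (mL).
#' @param label group label.
#' @return A `design_summary`: n, mean, sd, and standard error of the mean.
#' @export
design_summary <- function(volumes_ml, label = "") {
  volumes_ml <- as.numeric(volumes_ml)
  n <- length(volumes_ml)
  s <- if (n > 1) sd(volumes_ml) else 0
  structure(list(label = label, n = n,
                 mean_volume_ml = mean(volumes_ml),
                 sd_ml = s, sem_ml = s / sqrt(n),
                 volumes_ml = volumes_ml),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean %.2f mL, sd %.3f, SEM %.3f\n",
              if (nzchar(x$label)) x$label else "group",
              x$n, x$mean_volume_ml, x$sd_ml, x$sem_ml))
  invisible(x)
}

#' Compare two groups of stent volumes
#'
#' Welch two-sample t test plus per-group descriptive summaries; the
#' reusable core of a between-method volume comparison. Sign convention:
#' `mean_difference = mean(a) - mean(b)`, so swapping the arguments flips
#' the sign of the difference and of t.
#'
#' @param volumes_a,volumes_b numeric vectors (mL), each of length >= 2.
#' @param labels length-2 character vector of group labels.
#' @return A `group_comparison` with summaries, mean difference, Welch t,
#'   p value and 95 percent CI of the difference.
#' @export
compare_groups <- function(volumes_a, volumes_b, labels = c("A", "B")) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L)
    stop("each group needs at least 2 volumes")
  sa <- design_summary(volumes_a, labels[1])
  sb <- design_summary(volumes_b, labels[2])
  diff <- sa$mean_volume_ml - sb$mean_volume_ml
  if (sa$sd_ml == 0 && sb$sd_ml == 0) {
    tt <- list(statistic = c(t = if (diff == 0) 0 else sign(diff) * Inf),
               p.value = if (diff == 0) 1 else 0,
               conf.int = c(diff, diff))
  } else {
    tt <- t.test(volumes_a, volumes_b, var.equal = FALSE)
  }
  structure(list(summary_a = sa, summary_b = sb,
                 mean_difference = diff,
                 t = unname(tt$statistic), p_value = tt$p.value,
                 conf_int = as.numeric(tt$conf.int)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary_a); print(x$summary_b)
  cat(sprintf("mean difference %.3f mL (95%% CI %.3f, %.3f), Welch t = %.3f, p = %.4g\n",
              x$mean_difference, x$conf_int[1], x$conf_int[2], x$t, x$p_value))
  invisible(x)
}
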