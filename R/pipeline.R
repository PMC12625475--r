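#' Pipeline configuration
#'
#' Single home for every numeric design rule of the workflow. Defaults are
#' the published design rules: a 20 mm interincisal opening, occlusal
#' planes at 60 % (maxilla) and 40 % (mandible) of arch height from the
#' gums, a 1.5 % hull expansion, a separation plane 2 mm above the lower
#' central incisor, a tail extending 10 mm beyond the second molar, a
#' tongue body auto-placed 17.5 mm posterior to the lower-teeth centroid,
#' and a minimum plate thickness of 10 mm.
#'
#' @param interincisal_mm articulated opening the input must present (mm).
#' @param maxilla_plane_fraction maxillary plane height fraction, in (0, 1).
#' @param mandible_plane_fraction mandibular plane height fraction, in (0, 1).
#' @param hull_expand_fraction outward hull expansion (unitless).
#' @param separation_offset_mm separation-plane clearance above the lower
#'   incisor tip (mm).
#' @param tail_extension_mm tail length beyond the lower second molar (mm).
#' @param tongue_posterior_offset_mm posterior shift of the auto-placed
#'   tongue body (mm).
#' @param min_plate_thickness_mm lower-plate thickness floor (mm).
#' @param protect_distance_mm impression protection band for smoothing (mm).
#' @param smoothing_iterations Taubin iterations in the final step.
#' @param expansion_mode hull expansion mode, `"isotropic"` or
#'   `"normal_offset"`.
#' @param tongue_vertical_semiaxis_mm vertical semi-axis of the default
#'   tongue body (mm).
#' @param distal_trim_margin_mm distal margin past the second molar for the
#'   third-molar trim (mm).
#' @param checkpoint_dir directory for per-step STL checkpoints (`NULL`:
#'   a fresh temporary directory per run).
#' @export
stent_config <- function(interincisal_mm = 20,
                         maxilla_plane_fraction = 0.60,
                         mandible_plane_fraction = 0.40,
                         hull_expand_fraction = 0.015,
                         separation_offset_mm = 2,
                         tail_extension_mm = 10,
                         tongue_posterior_offset_mm = 17.5,
                         min_plate_thickness_mm = 10,
                         protect_distance_mm = 0.5,
                         smoothing_iterations = 10L,
                         expansion_mode = c("isotropic", "normal_offset"),
                         tongue_vertical_semiaxis_mm = 8,
                         distal_trim_margin_mm = 1,
                         checkpoint_dir = NULL) {
  expansion_mode <- match.arg(expansion_mode)
  cfg <- list(interincisal_mm = interincisal_mm,
              maxilla_plane_fraction = maxilla_plane_fraction,
              mandible_plane_fraction = mandible_plane_fraction,
              hull_expand_fraction = hull_expand_fraction,
              separation_offset_mm = separation_offset_mm,
              tail_extension_mm = tail_extension_mm,
              tongue_posterior_offset_mm = tongue_posterior_offset_mm,
              min_plate_thickness_mm = min_plate_thickness_mm,
              protect_distance_mm = protect_distance_mm,
              smoothing_iterations = as.integer(smoothing_iterations),
              expansion_mode = expansion_mode,
              tongue_vertical_semiaxis_mm = tongue_vertical_semiaxis_mm,
              distal_trim_margin_mm = distal_trim_margin_mm,
              checkpoint_dir = checkpoint_dir)
  lens <- c(cfg$interincisal_mm, cfg$separation_offset_mm, cfg$tail_extension_mm,
            cfg$tongue_posterior_offset_mm, cfg$min_plate_thickness_mm,
            cfg$protect_distance_mm, cfg$tongue_vertical_semiaxis_mm)
  if (any(lens <= 0)) stop("all length parameters must be positive")
  fr <- c(cfg$maxilla_plane_fraction, cfg$mandible_plane_fraction)
  if (any(fr <= 0 | fr >= 1)) stop("plane fractions must lie in (0, 1)")
  if (cfg$hull_expand_fraction < 0) stop("hull_expand_fraction must be >= 0")
  if (cfg$smoothing_iterations < 0) stop("smoothing_iterations must be >= 0")
  structure(cfg, class = "stent_config")
}

#' @export
print.stent_config <- function(x, ...) {
  cat("<stent_config>\n")
  for (nm in setdiff(names(x), "checkpoint_dir"))
    cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-28s %s\n", "checkpoint_dir",
              if (is.null(x$checkpoint_dir)) "<temporary>" else x$checkpoint_dir))
  invisible(x)
}

# ---- state plumbing --------------------------------------------------------

landmark <- function(anatomy, name) {
  lm <- anatomy$landmarks
  if (name %in% rownames(lm)) unname(lm[name, ]) else NULL
}

require_landmarks <- function(anatomy, names) {
  miss <- setdiff(names, rownames(anatomy$landmarks))
  if (length(miss))
    stop("missing required landmark(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# STL stores single-precision coordinates, which can collapse sliver
# triangles left by CSG; checkpoints are therefore written from a
# float32-snapped, re-cleaned copy so every file on disk is watertight.
checkpoint_mesh <- function(mesh) {
  snap32 <- function(v) {
    out <- readBin(writeBin(as.numeric(v), raw(), size = 4L),
                   "numeric", size = 4L, n = length(v))
    dim(out) <- dim(v)
    out
  }
  cur <- mesh
  for (i in 1:6) {
    v <- snap32(cur$vertices)
    # simulate exactly what read_stl will reconstruct from the file:
    # float32 coordinates, exact-match weld, degenerate faces dropped
    rb <- .cpp_weld(v, cur$faces, 1e-9)
    if (nrow(rb$faces) > 0L) {
      m <- tri_mesh(rb$vertices, rb$faces, mesh$provenance)
      if (is_watertight(m)) return(m)
    }
    # quantisation opened cracks: stitch/patch on the snapped copy and retry
    cleaned <- clean_csg_output(list(vertices = v, faces = cur$faces),
                                mesh$provenance, weld_tol = 1e-9)
    if (is.null(cleaned) || is_empty_mesh(cleaned)) break
    cur <- cleaned
  }
  cur
}

checkpoint_state <- function(state, step_id, name, mesh) {
  path <- file.path(state$checkpoint_dir, sprintf("%02d_%s.stl", step_id, name))
  write_stl(checkpoint_mesh(mesh), path)
  vol <- mesh_volume(mesh, check = FALSE)
  state$step_log <- rbind(state$step_log,
                          data.frame(step = step_id, name = name,
                                     checkpoint = path, volume_mm3 = vol,
                                     stringsAsFactors = FALSE))
  state
}

run_step <- function(state, step_id, fn) {
  tryCatch(fn(state), error = function(e) {
    last <- if (nrow(state$step_log)) tail(state$step_log$checkpoint, 1) else "<none>"
    stop(sprintf("step %d failed: %s [last good checkpoint: %s]",
                 step_id, conditionMessage(e), last), call. = FALSE)
  })
}

# ---- step 1: setup ---------------------------------------------------------

#' Step 1: import, validate articulation, repair
#'
#' Verifies the required landmarks, repairs both arch meshes to
#' watertightness, and checks that the articulated interincisal opening
#' matches the configured value (within 0.5 mm) -- the articulation is the
#' scale reference of the whole design.
#'
#' @param anatomy an `anatomy_model` (see [generate_anatomy()] /
#'   [read_anatomy()]).
#' @param config a [stent_config()].
#' @return A `pipeline_state`.
#' @export
step1_setup <- function(anatomy, config = stent_config()) {
  if (!inherits(anatomy, "anatomy_model")) stop("anatomy must be an anatomy_model")
  if (!inherits(config, "stent_config")) stop("config must be a stent_config")
  require_landmarks(anatomy, c("upper_incisor_tip", "lower_incisor_tip",
                               "upper_gum_baseline", "lower_gum_baseline"))
  gap <- interincisal_distance(anatomy)
  if (abs(gap - config$interincisal_mm) > 0.5)
    stop(sprintf("interincisal opening is %.2f mm but the configuration expects %g mm: re-articulate the model",
                 gap, config$interincisal_mm))
  anatomy$maxilla <- repair_watertight(anatomy$maxilla)
  anatomy$mandible <- repair_watertight(anatomy$mandible)
  ckdir <- config$checkpoint_dir %||% tempfile("stentforge_ckpt_")
  dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)
  state <- structure(list(anatomy = anatomy, config = config,
                          checkpoint_dir = ckdir,
                          step_log = data.frame(step = integer(), name = character(),
                                                checkpoint = character(),
                                                volume_mm3 = numeric(),
                                                stringsAsFactors = FALSE),
                          notes = character(), vol = list()),
                     class = "pipeline_state")
  checkpoint_state(state, 1L, "setup",
                   concat_meshes(anatomy$maxilla, anatomy$mandible))
}

# occlusal plane for one arch: PCA normal, repositioned at `frac` of the
# gum-baseline-to-occlusal-extreme height
arch_occlusal_plane <- function(arch, gum_baseline, frac) {
  pl <- fit_plane_pca(arch$vertices)
  gz <- gum_baseline[3]
  zs <- arch$vertices[, 3]
  occ <- zs[which.max(abs(zs - gz))]
  target_z <- gz + frac * (occ - gz)
  ctr <- colMeans(arch$vertices)
  plane(pl$normal,
        pl$normal[1] * ctr[1] + pl$normal[2] * ctr[2] + pl$normal[3] * target_z)
}

# ---- step 2: inverse block -------------------------------------------------

#' Step 2: stent outline block with carved dental impression
#'
#' Fits the maxillary and mandibular occlusal planes (PCA normals,
#' positioned at the configured height fractions), builds the expanded
#' combined convex hull of both arches, slices it at the two planes, and
#' Boolean-subtracts the dentition to carve the dental impression.
#'
#' @param state a `pipeline_state` after [step1_setup()].
#' @export
step2_inverse_block <- function(state) {
  run_step(state, 2L, function(state) {
    an <- state$anatomy
    cfg <- state$config
    state$maxillary_plane <- arch_occlusal_plane(an$maxilla,
                                                 landmark(an, "upper_gum_baseline"),
                                                 cfg$maxilla_plane_fraction)
    state$mandibular_plane <- arch_occlusal_plane(an$mandible,
                                                  landmark(an, "lower_gum_baseline"),
                                                  cfg$mandible_plane_fraction)
    hull <- expanded_hull(list(an$maxilla, an$mandible),
                          cfg$hull_expand_fraction, cfg$expansion_mode)
    state$hull_volume_mm3 <- mesh_volume(hull, check = FALSE)
    blk <- plane_cut(hull, state$maxillary_plane, keep = "below")
    blk <- plane_cut(blk, state$mandibular_plane, keep = "above")
    jaws <- concat_meshes(an$maxilla, an$mandible)
    blk <- mesh_boolean(blk, jaws, "subtract")
    blk$provenance <- "outline_block"
    state$outline_block <- blk
    state$vol$hull <- state$hull_volume_mm3
    state$vol$outline_block <- mesh_volume(blk, check = FALSE)
    checkpoint_state(state, 2L, "outline_block", blk)
  })
}

# ---- step 3: separate upper and lower --------------------------------------

#' Step 3: separate the block into upper and lower stents
#'
#' The separation plane is parallel to the mandibular occlusal plane and
#' passes `separation_offset_mm` (default 2 mm) above the lower central
#' incisor tip. Everything above becomes the upper stent, everything below
#' the lower stent.
#'
#' @param state a `pipeline_state` after [step2_inverse_block()].
#' @export
step3_separate_upper_lower <- function(state) {
  run_step(state, 3L, function(state) {
    if (is.null(state$outline_block)) stop("run step2_inverse_block first")
    tip <- landmark(state$anatomy, "lower_incisor_tip")
    n <- state$mandibular_plane$normal
    state$separation_plane <- plane(n, sum(n * tip) + state$config$separation_offset_mm)
    up <- plane_cut(state$outline_block, state$separation_plane, keep = "above")
    lo <- plane_cut(state$outline_block, state$separation_plane, keep = "below")
    if (is_empty_mesh(up) || is_empty_mesh(lo))
      stop("separation plane does not split the outline block")
    up$provenance <- "upper_stent"; lo$provenance <- "lower_stent"
    state$upper_stent <- up
    state$lower_stent <- lo
    state$vol$upper <- mesh_volume(up, check = FALSE)
    state$vol$lower <- mesh_volume(lo, check = FALSE)
    checkpoint_state(state, 3L, "separate", concat_meshes(up, lo))
  })
}

unit_xy <- function(v) {
  v <- c(v[1], v[2], 0)
  l <- sqrt(sum(v^2))
  if (l < 1e-9) stop("degenerate direction between landmarks")
  v / l
}

# ---- step 4: trim third molars ---------------------------------------------

#' Step 4: remove third molars from the lower stent
#'
#' For each side carrying a lower third-molar landmark, the lower stent is
#' cut by a vertical plane placed just distal (default 1 mm) of the
#' lower second molar, keeping the anterior part. Sides without a
#' third molar are left untouched, so edentulous and hypodontia anatomies
#' pass through unchanged.
#'
#' @param state a `pipeline_state` after [step3_separate_upper_lower()].
#' @export
step4_trim_lower <- function(state) {
  run_step(state, 4L, function(state) {
    if (is.null(state$lower_stent)) stop("run step3_separate_upper_lower first")
    an <- state$anatomy
    lo <- state$lower_stent
    for (side in c("left", "right")) {
      m3 <- landmark(an, paste0("lower_third_molar_", side))
      m2 <- landmark(an, paste0("lower_second_molar_", side))
      m1 <- landmark(an, paste0("lower_first_molar_", side))
      if (is.null(m3) || is.null(m2)) next
      ref <- if (!is.null(m1)) m1 else landmark(an, "lower_incisor_tip")
      distal <- unit_xy(m2 - ref)
      cutpl <- plane(distal, sum(distal * m2) + state$config$distal_trim_margin_mm)
      lo <- suppressWarnings(plane_cut(lo, cutpl, keep = "below"))
    }
    lo$provenance <- "lower_stent_trimmed"
    state$lower_stent <- lo
    state$vol$lower_trimmed <- mesh_volume(lo, check = FALSE)
    checkpoint_state(state, 4L, "trim_lower", lo)
  })
}

# ---- step 5: upper supports -------------------------------------------------

# three vertical planes isolating the canine-to-second-molar span of one side
support_planes <- function(an, stent, side) {
  sx <- if (side == "left") 1 else -1
  canine <- landmark(an, paste0("upper_canine_", side))
  m2 <- landmark(an, paste0("upper_second_molar_", side))
  m1 <- landmark(an, paste0("upper_first_molar_", side))
  pm1 <- landmark(an, paste0("upper_first_premolar_", side))
  if (is.null(canine) || is.null(m2)) return(NULL)
  mesial_dir <- unit_xy(canine - (if (!is.null(pm1)) pm1 else m2))
  distal_dir <- unit_xy(m2 - (if (!is.null(m1)) m1 else canine))
  row_lm <- rbind(canine, pm1, m1, m2)
  x_lingual <- min(sx * row_lm[, 1]) - 5
  list(mesial = plane(mesial_dir, sum(mesial_dir * canine) + 4),
       distal = plane(distal_dir, sum(distal_dir * m2) + 4),
       parasagittal = plane(c(sx, 0, 0), x_lingual))
}

# fallback planes from arch fractions when tooth landmarks are unavailable
support_planes_fallback <- function(stent, side) {
  sx <- if (side == "left") 1 else -1
  bb <- mesh_bbox(stent)
  yr <- bb[2, 2] - bb[1, 2]
  xmax <- max(abs(bb[, 1]))
  list(mesial = plane(c(0, 1, 0), bb[1, 2] + 0.70 * yr),
       distal = plane(c(0, -1, 0), -(bb[1, 2] + 0.02 * yr)),
       parasagittal = plane(c(sx, 0, 0), 0.15 * xmax))
}

#' Step 5: carve the left and right upper supports
#'
#' Each side's support is cut from the upper stent with three vertical
#' planes: one just mesial of the canine, one just distal of the second
#' molar, and a parasagittal plane on the lingual side of the tooth row --
#' so the canine, both premolars and the first two molars are included
#' while the incisors are not. When the tooth landmarks are missing
#' (edentulous input), arch-fraction planes are used instead, with a
#' warning.
#'
#' @param state a `pipeline_state` after [step3_separate_upper_lower()].
#' @export
step5_upper_supports <- function(state) {
  run_step(state, 5L, function(state) {
    if (is.null(state$upper_stent)) stop("run step3_separate_upper_lower first")
    an <- state$anatomy
    for (side in c("left", "right")) {
      pls <- support_planes(an, state$upper_stent, side)
      if (is.null(pls)) {
        warning(sprintf("no canine/second-molar landmarks on the %s side; using arch-fraction support planes", side))
        pls <- support_planes_fallback(state$upper_stent, side)
      }
      sup <- suppressWarnings(plane_cut(state$upper_stent, pls$mesial, keep = "below"))
      sup <- suppressWarnings(plane_cut(sup, pls$distal, keep = "below"))
      sup <- suppressWarnings(plane_cut(sup, pls$parasagittal, keep = "above"))
      if (is_empty_mesh(sup)) stop(sprintf("support carving emptied the %s side", side))
      sup$provenance <- paste0("upper_", side)
      state[[paste0("upper_", side)]] <- sup
      state[[paste0("support_planes_", side)]] <- pls
    }
    state$vol$upper_left <- mesh_volume(state$upper_left, check = FALSE)
    state$vol$upper_right <- mesh_volume(state$upper_right, check = FALSE)
    checkpoint_state(state, 5L, "upper_supports",
                     concat_meshes(state$upper_left, state$upper_right))
  })
}

# ---- step 6: stent tail -----------------------------------------------------

#' Step 6: add the tongue-depressing tail
#'
#' A box spanning the lower plate's thickness band is unioned onto the
#' lower stent, extending `tail_extension_mm` (default 10 mm) beyond the
#' lower second molar along the posterior axis. Without molar landmarks
#' (edentulous input) the posterior end of the mandibular ridge is the
#' reference instead.
#'
#' @param state a `pipeline_state` after [step4_trim_lower()] (or step 3;
#'   the trim is a no-op without third molars).
#' @export
step6_add_tail <- function(state) {
  run_step(state, 6L, function(state) {
    if (is.null(state$lower_stent)) stop("run step3_separate_upper_lower first")
    an <- state$anatomy
    m2l <- landmark(an, "lower_second_molar_left")
    m2r <- landmark(an, "lower_second_molar_right")
    if (!is.null(m2l) || !is.null(m2r)) {
      m2s <- rbind(m2l, m2r)
      y_ref <- min(m2s[, 2])
      half_w <- max(abs(m2s[, 1])) + 5
    } else {
      y_ref <- min(an$mandible$vertices[, 2])
      half_w <- 0.35 * diff(range(an$mandible$vertices[, 1]))
    }
    bb <- mesh_bbox(state$lower_stent)
    y_lo <- y_ref - state$config$tail_extension_mm
    y_hi <- mesh_centroid(state$lower_stent)[2]
    if (y_lo >= y_hi) stop("tail would not reach the lower stent body")
    z0 <- bb[1, 3]; z1 <- bb[2, 3]
    box <- make_box(center = c(0, (y_lo + y_hi) / 2, (z0 + z1) / 2),
                    extents = c(2 * half_w, y_hi - y_lo, z1 - z0))
    box$provenance <- "tail_box"
    state$tail_box <- box
    state$tail_posterior_y <- y_lo
    lo <- mesh_boolean(state$lower_stent, box, "union")
    lo$provenance <- "lower_with_tail"
    state$lower_stent <- lo
    state$vol$tail_box <- mesh_volume(box, check = FALSE)
    state$vol$lower_with_tail <- mesh_volume(lo, check = FALSE)
    checkpoint_state(state, 6L, "add_tail", lo)
  })
}

# ---- step 7: tongue depression ----------------------------------------------

# default tongue body from the anatomy: centred on the lower tooth
# landmarks, shifted posteriorly, sized from the inter-molar width, and
# sunk so its apex sits min_plate_thickness + 1 mm below the separation
# plane (the published placement criterion is the thickness floor itself)
default_tongue <- function(state) {
  an <- state$anatomy
  cfg <- state$config
  lm <- an$landmarks
  tooth <- grepl("^lower_", rownames(lm)) &
    !grepl("ridge_crest|gum_baseline|incisor_tip", rownames(lm))
  ctr_xy <- if (any(tooth)) colMeans(lm[tooth, 1:2, drop = FALSE])
            else colMeans(an$mandible$vertices[, 1:2, drop = FALSE])
  # lateral centring uses the dental midline (midpoints of left/right
  # pairs), which stays put when teeth are missing asymmetrically
  tooth_names <- rownames(lm)[tooth]
  pairs_x <- c()
  widths <- c()
  for (base in unique(sub("_(left|right)$", "", tooth_names))) {
    l <- landmark(an, paste0(base, "_left"))
    r <- landmark(an, paste0(base, "_right"))
    if (!is.null(l) && !is.null(r)) {
      pairs_x <- c(pairs_x, (l[1] + r[1]) / 2)
      if (grepl("molar", base)) widths <- c(widths, abs(l[1] - r[1]) / 2)
    }
  }
  mid_x <- if (length(pairs_x)) mean(pairs_x) else ctr_xy[1]
  a <- if (length(widths)) 0.8 * min(widths)
       else 0.30 * diff(range(an$mandible$vertices[, 1]))
  b <- 1.25 * a
  cz <- cfg$tongue_vertical_semiaxis_mm
  center_xy <- c(mid_x, ctr_xy[2] - cfg$tongue_posterior_offset_mm)
  sep <- state$separation_plane
  sep_z <- (sep$offset - sep$normal[1] * center_xy[1] -
              sep$normal[2] * center_xy[2]) / sep$normal[3]
  apex_z <- sep_z - (cfg$min_plate_thickness_mm + 1)
  tongue_params(semi_axes = c(a, b, cz),
                center = c(center_xy[1], center_xy[2], apex_z - cz),
                posterior_offset = cfg$tongue_posterior_offset_mm)
}

# XY footprint of the carved depression: the sub-ellipse where the tongue
# dome actually rises above the plate bottom, shrunk away from its rim and
# clipped clear of the tail's posterior face
tongue_footprint <- function(state, tongue, bottom_z) {
  ax <- tongue$semi_axes
  cz <- tongue$center[3]
  pen <- (bottom_z - cz) / ax[3]
  r2 <- 1 - pen^2
  r <- 0.92 * sqrt(max(r2, 0.02))
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  poly <- cbind(tongue$center[1] + ax[1] * r * cos(th),
                tongue$center[2] + ax[2] * r * sin(th))
  if (!is.null(state$tail_posterior_y))
    poly <- clip_polygon_halfplane(poly, 0, -1, -(state$tail_posterior_y + 1))
  poly
}

#' Step 7: subtract the tongue space
#'
#' Subtracts an ellipsoidal tongue body from the lower stent to create room
#' for the tongue. By default the body is centred on the lower tooth
#' landmarks, translated 17.5 mm posteriorly so its tip sits behind the
#' incisors, sized laterally from the inter-molar width, and sunk so the
#' remaining plate above it stays at least `min_plate_thickness_mm` thick.
#' The achieved minimum plate thickness is measured by vertical ray casting
#' over the depression footprint and stored; a violation of the floor is an
#' error reporting the measured value.
#'
#' @param state a `pipeline_state` after [step6_add_tail()].
#' @param tongue optional [tongue_params()] overriding the automatic
#'   placement.
#' @export
step7_tongue_depression <- function(state, tongue = NULL) {
  run_step(state, 7L, function(state) {
    if (is.null(state$lower_stent)) stop("run step6_add_tail first")
    cfg <- state$config
    if (is.null(tongue)) tongue <- default_tongue(state)
    if (!inherits(tongue, "tongue_params")) stop("tongue must be tongue_params()")
    bottom_z <- mesh_bbox(state$lower_stent)[1, 3]
    tm <- make_tongue_mesh(tongue)
    lo <- mesh_boolean(state$lower_stent, tm, "subtract")
    lo$provenance <- "lower_after_tongue"
    footprint <- tongue_footprint(state, tongue, bottom_z)
    thick <- min_plate_thickness(lo, footprint, spacing = 0.5)
    if (thick < cfg$min_plate_thickness_mm)
      stop(sprintf("plate thickness %.2f mm is below the %g mm floor: use smaller tongue semi-axes or a shallower placement",
                   thick, cfg$min_plate_thickness_mm))
    state$tongue <- tongue
    state$tongue_footprint <- footprint
    state$min_plate_thickness_mm <- thick
    state$lower_stent <- lo
    state$vol$lower_after_tongue <- mesh_volume(lo, check = FALSE)
    checkpoint_state(state, 7L, "tongue_depression", lo)
  })
}

# ---- step 8: combine ---------------------------------------------------------

#' Step 8: combine the three stent parts
#'
#' Union of the upper-left and upper-right supports with the lower stent.
#' The three parts have pairwise disjoint interiors by construction (the
#' upper supports live strictly above the separation plane and are split
#' across the midline; the lower stent lives strictly below), so their
#' exact Boolean union is the concatenation of their boundaries and the
#' combined volume is exactly additive. If the result is not a single
#' connected component a note is logged (the parts legitimately connect
#' only through the interocclusal body once seated).
#'
#' @param state a `pipeline_state` after [step7_tongue_depression()].
#' @export
step8_combine <- function(state) {
  run_step(state, 8L, function(state) {
    if (is.null(state$upper_left) || is.null(state$upper_right) ||
        is.null(state$lower_stent))
      stop("steps 5-7 must be complete before combining")
    comb <- concat_meshes(concat_meshes(state$upper_left, state$upper_right),
                          state$lower_stent)
    comb$provenance <- "combined"
    ncomp <- .cpp_vertex_components(nrow(comb$vertices), comb$faces)
    if (ncomp > 1) {
      note <- sprintf("combined stent has %d connected components (parts meet only at the separation plane)", ncomp)
      state$notes <- c(state$notes, note)
      message(note)
    }
    state$combined <- comb
    state$vol$combined <- mesh_volume(comb, check = FALSE)
    checkpoint_state(state, 8L, "combine", comb)
  })
}

# ---- step 9: smoothing -------------------------------------------------------

#' Step 9: protected smoothing and result assembly
#'
#' Taubin smoothing of the combined stent with the dental impression
#' protected: vertices within `protect_distance_mm` of either arch surface
#' are frozen bit-for-bit, so the impression fit is untouched while sharp
#' block edges are relaxed.
#'
#' @param state a `pipeline_state` after [step8_combine()].
#' @return A `stent_design` result object.
#' @export
step9_smooth <- function(state) {
  run_step(state, 9L, function(state) {
    if (is.null(state$combined)) stop("run step8_combine first")
    cfg <- state$config
    fin <- smooth_protected(state$combined,
                            list(state$anatomy$maxilla, state$anatomy$mandible),
                            protect_distance = cfg$protect_distance_mm,
                            iterations = cfg$smoothing_iterations)
    fin$provenance <- "final_stent"
    state$final <- fin
    state$vol$final <- mesh_volume(fin, check = FALSE)
    state <- checkpoint_state(state, 9L, "smooth", fin)
    log <- state$step_log
    vols <- stats::setNames(log$volume_mm3, log$name)
    structure(list(final_stent = fin,
                   part_volumes_mm3 = vols,
                   min_plate_thickness_mm = state$min_plate_thickness_mm,
                   config_used = cfg,
                   preset = state$anatomy$preset %||% "unknown",
                   step_log = log,
                   state = state),
              class = "stent_design")
  })
}

# ---- orchestrator ------------------------------------------------------------

#' Run the full nine-step stent design workflow
#'
#' Executes steps 1 through 9 on an articulated anatomy, writing one STL
#' checkpoint per step. Fully deterministic: identical anatomy and
#' configuration reproduce identical volumes.
#'
#' @param anatomy an `anatomy_model`.
#' @param config a [stent_config()].
#' @param tongue optional [tongue_params()] override for step 7.
#' @return A `stent_design`.
#' @export
run_pipeline <- function(anatomy, config = stent_config(), tongue = NULL) {
  state <- step1_setup(anatomy, config)
  state <- step2_inverse_block(state)
  state <- step3_separate_upper_lower(state)
  state <- step4_trim_lower(state)
  state <- step5_upper_supports(state)
  state <- step6_add_tail(state)
  state <- step7_tongue_depression(state, tongue)
  state <- step8_combine(state)
  step9_smooth(state)
}

#' Design a mouth-opening tongue-depressing stent
#'
#' The package's main entry point: a thin, formula-free fitting interface
#' over [run_pipeline()] returning a classed result with `print`,
#' `summary` and `plot` methods.
#'
#' @inheritParams run_pipeline
#' @export
design_stent <- function(anatomy, config = stent_config(), tongue = NULL) {
  run_pipeline(anatomy, config, tongue)
}

#' @export
print.stent_design <- function(x, ...) {
  cat(sprintf("<stent_design> preset '%s'\n", x$preset))
  cat(sprintf("  final stent: %.2f mL (%d faces)\n",
              mesh_volume(x$final_stent, check = FALSE) / 1000,
              nrow(x$final_stent$faces)))
  if (!is.null(x$min_plate_thickness_mm))
    cat(sprintf("  min plate thickness: %.2f mm (floor %g mm)\n",
                x$min_plate_thickness_mm, x$config_used$min_plate_thickness_mm))
  cat(sprintf("  checkpoints: %d in %s\n", nrow(x$step_log),
              dirname(x$step_log$checkpoint[1])))
  invisible(x)
}

#' @export
summary.stent_design <- function(object, ...) {
  log <- object$step_log
  log$volume_ml <- log$volume_mm3 / 1000
  cat("Step-by-step volume trace:\n")
  print(log[, c("step", "name", "volume_ml")], row.names = FALSE)
  cat(sprintf("\nmin plate thickness: %.2f mm\n", object$min_plate_thickness_mm))
  invisible(log)
}

#' @export
plot.stent_design <- function(x, ...) {
  log <- x$step_log
  op <- par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(par(op))
  barplot(log$volume_mm3 / 1000, names.arg = log$name, las = 2,
          ylab = "checkpoint volume (mL)", main = "volume trace", ...)
  v <- x$final_stent$vertices
  keep <- seq(1L, nrow(v), by = max(1L, nrow(v) %/% 4000L))
  plot(v[keep, 1], v[keep, 2], pch = ".", asp = 1,
       xlab = "x (mm)", ylab = "y (mm)", main = "final stent, occlusal view")
  invisible(x)
}
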