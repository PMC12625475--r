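#' Parameters for the synthetic dental-anatomy generator
#'
#' Defaults describe a plausible adult arch scanned as a stone model:
#' 55 mm wide, 45 mm deep, 12 mm of gum/alveolar ridge below 8 mm tooth
#' crowns, articulated at a 20 mm interincisal opening.
#'
#' @param arch_width_mm outer arch width (mm).
#' @param arch_depth_mm anteroposterior arch depth (mm).
#' @param tooth_height_mm nominal crown height above the gum line (mm).
#' @param ridge_height_mm gum/alveolar ridge height above the model base (mm).
#' @param interincisal_mm articulated opening between incisor tips (mm).
#' @param jitter_mm seeded uniform jitter applied to tooth heights and
#'   stations (mm); never applied to landmark/mesh consistency.
#' @param third_molars include third-molar stations on the mandible
#'   (default `FALSE`; enable to exercise the third-molar trimming step).
#' @export
anatomy_params <- function(arch_width_mm = 55, arch_depth_mm = 45,
                           tooth_height_mm = 8, ridge_height_mm = 12,
                           interincisal_mm = 20, jitter_mm = 0.2,
                           third_molars = FALSE) {
  p <- list(arch_width_mm = arch_width_mm, arch_depth_mm = arch_depth_mm,
            tooth_height_mm = tooth_height_mm, ridge_height_mm = ridge_height_mm,
            interincisal_mm = interincisal_mm, jitter_mm = jitter_mm,
            third_molars = isTRUE(third_molars))
  lens <- unlist(p[1:5])
  if (any(lens <= 0)) stop("all anatomy lengths must be positive")
  if (jitter_mm < 0) stop("jitter_mm must be non-negative")
  structure(p, class = "anatomy_params")
}

# tooth stations along one half-arch: nominal arc-length centre (mm from the
# midline) and mesiodistal width, scaled to the actual half-arch length
.tooth_table <- function() {
  data.frame(
    tooth = c("central_incisor", "lateral_incisor", "canine", "first_premolar",
              "second_premolar", "first_molar", "second_molar", "third_molar"),
    center = c(4.25, 11.75, 18.75, 26, 33, 41.75, 52, 61.5),
    width = c(8.5, 6.5, 7.5, 7, 7, 10.5, 10, 9.5),
    rel_height = c(1, 0.95, 1.05, 0.9, 0.9, 0.8, 0.8, 0.75),
    stringsAsFactors = FALSE)
}

# arch centreline: x = (W/2) t, y = D (1 - t^2), t in [-1, 1]
.arch_curve <- function(W, D, t) {
  cbind(x = W / 2 * t, y = D * (1 - t^2))
}

.arch_arclength <- function(W, D, t) {
  # cumulative arc length from t = 0, signed with t
  f <- function(u) sqrt((W / 2)^2 + (2 * D * u)^2)
  vapply(t, function(ti) {
    s <- sign(ti)
    if (ti == 0) return(0)
    u <- seq(0, abs(ti), length.out = 257L)
    s * sum((f(u[-1]) + f(u[-length(u)])) / 2 * diff(u))
  }, numeric(1))
}

# invert arc length -> t on a dense monotone table
.arc_to_t <- function(W, D, arc) {
  tt <- seq(-1, 1, length.out = 2049L)
  aa <- .arch_arclength(W, D, tt)
  stats::approx(aa, tt, xout = arc, rule = 2)$y
}

# Build one arch solid as a closed height-field band: top surface = rounded
# gum ridge plus superellipsoid-profile tooth cusps, flat base at z = 0,
# walls around the rim. Watertight by construction; landmarks are exact
# surface vertices.
.build_arch <- function(params, stations, arch_label, half_width = 5,
                        nt = 160L, ns = 14L) {
  W <- params$arch_width_mm
  D <- params$arch_depth_mm
  ridge <- params$ridge_height_mm

  L_half <- .arch_arclength(W, D, 1)
  arcs_uniform <- seq(-L_half, L_half, length.out = nt + 1L)
  arcs <- sort(unique(c(arcs_uniform, 0, if (nrow(stations)) stations$arc)))
  tg <- .arc_to_t(W, D, arcs)
  sg <- seq(-1, 1, length.out = ns + 1L)

  ctr <- .arch_curve(W, D, tg)
  # unit tangent and left normal of the centreline
  dx <- W / 2
  dy <- -2 * D * tg
  tl <- sqrt(dx^2 + dy^2)
  nxv <- -dy / tl
  nyv <- dx / tl

  ntt <- length(tg); nss <- length(sg)
  X <- outer(ctr[, 1], rep(1, nss)) + outer(nxv, sg * half_width)
  Y <- outer(ctr[, 2], rep(1, nss)) + outer(nyv, sg * half_width)
  Ztop <- matrix(ridge, ntt, nss)
  Ztop <- Ztop * (1 - 0.3 * outer(rep(1, ntt), sg^2))
  if (nrow(stations)) {
    arc_mat <- outer(arcs, rep(1, nss))
    s_mm <- outer(rep(1, ntt), sg * half_width)
    for (k in seq_len(nrow(stations))) {
      st <- stations[k, ]
      u <- (arc_mat - st$arc) / st$r_arc
      w <- s_mm / st$r_trans
      bump <- 1 - u^2 - w^2
      bump[bump < 0] <- 0
      Ztop <- Ztop + st$height * bump^1.5
    }
  }

  vid <- function(i, j) i + (j - 1L) * ntt
  top <- cbind(as.vector(X), as.vector(Y), as.vector(Ztop))
  bot <- cbind(as.vector(X), as.vector(Y), 0)
  verts <- rbind(top, bot)
  off <- ntt * nss

  faces <- vector("list", 6L)
  i <- rep(seq_len(ntt - 1L), nss - 1L)
  j <- rep(seq_len(nss - 1L), each = ntt - 1L)
  a <- vid(i, j); b <- vid(i + 1L, j); cc <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
  faces[[1]] <- cbind(a, b, cc)
  faces[[2]] <- cbind(a, cc, d)
  faces[[3]] <- cbind(a + off, cc + off, b + off)
  faces[[4]] <- cbind(a + off, d + off, cc + off)
  # walls along s = +/-1
  iw <- seq_len(ntt - 1L)
  for (jw in c(1L, nss)) {
    a <- vid(iw, jw); b <- vid(iw + 1L, jw)
    faces[[length(faces) + 1L]] <- cbind(a, b, b + off)
    faces[[length(faces) + 1L]] <- cbind(a, b + off, a + off)
  }
  # walls at the two arch ends
  jw <- seq_len(nss - 1L)
  for (ie in c(1L, ntt)) {
    a <- vid(ie, jw); b <- vid(ie, jw + 1L)
    faces[[length(faces) + 1L]] <- cbind(a, b, b + off)
    faces[[length(faces) + 1L]] <- cbind(a, b + off, a + off)
  }
  f <- do.call(rbind, faces)
  m <- weld_mesh(tri_mesh(verts, f, arch_label))
  o <- .cpp_orient(m$vertices, m$faces)
  m <- tri_mesh(m$vertices, o$faces, arch_label)

  # landmarks: tooth apices (exact grid vertices at s = 0, t = station t)
  lm <- list()
  if (nrow(stations)) {
    for (k in seq_len(nrow(stations))) {
      st <- stations[k, ]
      ti <- which.min(abs(arcs - st$arc))
      j0 <- which(sg == 0)
      vi <- vid(ti, j0)
      lm[[paste0(arch_label, "_", st$tooth, "_", st$side)]] <-
        c(X[ti, j0], Y[ti, j0], Ztop[ti, j0])
    }
  }
  # anterior ridge-crest point at the midline (used as the incisor-tip
  # stand-in on edentulous arches)
  ti0 <- which.min(abs(arcs)); j0 <- which(sg == 0)
  lm[[paste0(arch_label, "_ridge_crest")]] <- c(X[ti0, j0], Y[ti0, j0], Ztop[ti0, j0])
  lm[[paste0(arch_label, "_gum_baseline")]] <- c(X[ti0, j0], Y[ti0, j0], 0)
  list(mesh = m, landmarks = lm)
}

# per-arch station table for a preset, with seeded jitter applied
.make_stations <- function(params, preset, third_molars) {
  tab <- .tooth_table()
  if (!third_molars) tab <- tab[tab$tooth != "third_molar", ]
  L_half <- .arch_arclength(params$arch_width_mm, params$arch_depth_mm, 1)
  scale <- min(1, (L_half - 2) / (max(tab$center) + max(tab$width) / 2))
  both <- rbind(transform(tab, side = "right", arc = -center * scale),
                transform(tab, side = "left", arc = center * scale))
  both$r_arc <- 0.48 * both$width * scale
  both$r_trans <- 4.5
  both$height <- params$tooth_height_mm * both$rel_height
  j <- params$jitter_mm
  n <- nrow(both)
  if (j > 0) {
    both$height <- both$height + runif(n, -j, j)
    both$arc <- both$arc + runif(n, -j, j)
  } else {
    runif(2 * n) # keep the RNG stream aligned across jitter settings
  }
  both
}

#' Generate a synthetic articulated dental anatomy
#'
#' Deterministic parametric stand-in for an intraoral scan of articulated
#' stone models: maxilla and mandible as watertight height-field arch solids
#' (swept gum ridge carrying superellipsoid-profile tooth cusps at up to 16
#' stations per arch) plus a named landmark set (tooth apices, anterior
#' ridge crest, gum baselines). Identical parameters and seed reproduce the
#' model bit for bit.
#'
#' Presets span the anatomy spectrum the design workflow must cope with:
#' `"normal"` (full dentition), `"edentulous"` (ridge only),
#' `"hypodontia"` (a seeded subset of 3 stations removed per arch from the
#' 10 congenitally-missing-prone candidates: lateral incisors, premolars,
#' first/second molars), and `"class3"` (mandible advanced 6 mm
#' anteriorly).
#'
#' @param preset one of `"normal"`, `"edentulous"`, `"hypodontia"`,
#'   `"class3"`.
#' @param seed integer seed for the jitter stream.
#' @param params an [anatomy_params()].
#' @return An object of class `anatomy_model`: fields `maxilla`, `mandible`
#'   ([tri_mesh()]), `landmarks` (named matrix, mm), `preset`, `seed`.
#' @export
generate_anatomy <- function(preset = c("normal", "edentulous", "hypodontia", "class3"),
                             seed = 1L, params = anatomy_params()) {
  preset <- match.arg(preset)
  if (!inherits(params, "anatomy_params")) stop("params must be anatomy_params()")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  # an edentulous stone model retains the full alveolar ridge: without
  # crowns, the scanned base is taller than the dentate gum line
  if (preset == "edentulous")
    params$ridge_height_mm <- params$ridge_height_mm + 6

  class3_advance <- 6

  build_one <- function(arch_label) {
    third <- params$third_molars && arch_label == "lower" &&
      preset %in% c("normal", "class3")
    if (preset == "edentulous") {
      stations <- .make_stations(params, preset, third)[0, ]
    } else {
      stations <- .make_stations(params, preset, third)
      if (preset == "hypodontia") {
        pool <- c("lateral_incisor", "first_premolar", "second_premolar",
                  "first_molar", "second_molar")
        cand <- which(stations$tooth %in% pool)
        drop <- sample(cand, 3L)
        stations <- stations[-drop, ]
      }
    }
    .build_arch(params, stations, arch_label)
  }

  lower <- build_one("lower")
  upper <- build_one("upper")

  # reflect the upper arch so its teeth point down, then raise it so the
  # incisor tips are interincisal_mm apart
  tip_l <- if (!is.null(lower$landmarks[["lower_central_incisor_right"]]))
    lower$landmarks[["lower_central_incisor_right"]] else
    lower$landmarks[["lower_ridge_crest"]]
  tip_u_raw <- if (!is.null(upper$landmarks[["upper_central_incisor_right"]]))
    upper$landmarks[["upper_central_incisor_right"]] else
    upper$landmarks[["upper_ridge_crest"]]
  Tz <- tip_l[3] + params$interincisal_mm + tip_u_raw[3]
  mx <- upper$mesh
  mx$vertices[, 3] <- Tz - mx$vertices[, 3]
  mx$faces <- mx$faces[, c(1L, 3L, 2L)]
  mx$provenance <- "maxilla"
  upper$landmarks <- lapply(upper$landmarks, function(p) c(p[1], p[2], Tz - p[3]))

  md <- lower$mesh
  md$provenance <- "mandible"
  if (preset == "class3") {
    md$vertices[, 2] <- md$vertices[, 2] + class3_advance
    lower$landmarks <- lapply(lower$landmarks, function(p)
      c(p[1], p[2] + class3_advance, p[3]))
  }

  lm <- c(lower$landmarks, upper$landmarks)
  lm[["lower_incisor_tip"]] <-
    if (!is.null(lm[["lower_central_incisor_right"]]))
      lm[["lower_central_incisor_right"]] else lm[["lower_ridge_crest"]]
  lm[["upper_incisor_tip"]] <-
    if (!is.null(lm[["upper_central_incisor_right"]]))
      lm[["upper_central_incisor_right"]] else lm[["upper_ridge_crest"]]
  lmm <- do.call(rbind, lm)
  colnames(lmm) <- c("x", "y", "z")

  # snap to float32-representable coordinates: STL stores single precision,
  # so generated models survive checkpointing bit for bit
  snap32 <- function(x) {
    d <- dim(x)
    out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                   "numeric", size = 4L, n = length(x))
    dim(out) <- d
    out
  }
  mx$vertices <- snap32(mx$vertices)
  md$vertices <- snap32(md$vertices)
  lmm2 <- snap32(lmm)
  dimnames(lmm2) <- dimnames(lmm)
  lmm <- lmm2

  structure(list(maxilla = mx, mandible = md, landmarks = lmm,
                 preset = preset, seed = as.integer(seed), params = params),
            class = "anatomy_model")
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("<anatomy_model> preset '%s', seed %d\n", x$preset, x$seed))
  cat(sprintf("  maxilla:  %d faces | mandible: %d faces | %d landmarks\n",
              nrow(x$maxilla$faces), nrow(x$mandible$faces), nrow(x$landmarks)))
  cat(sprintf("  interincisal opening: %.2f mm\n", interincisal_distance(x)))
  invisible(x)
}

#' Interincisal distance of an articulated model
#'
#' Vertical (occlusal-axis) gap between the upper and lower incisor-tip
#' landmarks.
#'
#' @param model an `anatomy_model`.
#' @export
interincisal_distance <- function(model) {
  lm <- model$landmarks
  need <- c("upper_incisor_tip", "lower_incisor_tip")
  miss <- setdiff(need, rownames(lm))
  if (length(miss)) stop("missing landmark(s): ", paste(miss, collapse = ", "))
  lm["upper_incisor_tip", "z"] - lm["lower_incisor_tip", "z"]
}

#' Re-articulate a model to a target interincisal opening
#'
#' Rigid vertical translation of the mandible (and its landmarks) so the
#' incisor-tip gap equals `interincisal_mm`. Path independent: articulating
#' to 25 then 20 mm equals articulating straight to 20 mm.
#'
#' @param model an `anatomy_model`.
#' @param interincisal_mm target opening (mm).
#' @export
articulate <- function(model, interincisal_mm) {
  gap <- interincisal_distance(model)
  dz <- gap - interincisal_mm
  model$mandible$vertices[, 3] <- model$mandible$vertices[, 3] + dz
  lower <- grepl("^lower_", rownames(model$landmarks))
  model$landmarks[lower, "z"] <- model$landmarks[lower, "z"] + dz
  model
}

#' Write an anatomy model as STL + landmark sidecar files
#'
#' Writes `maxilla.stl`, `mandible.stl` and `landmarks.json` (schema:
#' `{"landmarks": {name: [x,y,z]}, "units": "mm", "preset": ..., "seed": ...}`).
#' The same sidecar schema is the input format for real scan landmarks.
#'
#' @param model an `anatomy_model`.
#' @param dir output directory (created if needed).
#' @export
write_anatomy <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stl(model$maxilla, file.path(dir, "maxilla.stl"))
  write_stl(model$mandible, file.path(dir, "mandible.stl"))
  lm <- lapply(seq_len(nrow(model$landmarks)),
               function(i) unname(model$landmarks[i, ]))
  names(lm) <- rownames(model$landmarks)
  jsonlite::write_json(list(landmarks = lm, units = "mm",
                            preset = model$preset, seed = model$seed),
                       file.path(dir, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an anatomy model from a directory
#'
#' Expects `maxilla.stl`, `mandible.stl` and `landmarks.json` as written by
#' [write_anatomy()] (or produced from real scans). Meshes are repaired to
#' watertightness on load.
#'
#' @param dir directory path.
#' @export
read_anatomy <- function(dir) {
  mx <- repair_watertight(read_stl(file.path(dir, "maxilla.stl"), "maxilla"))
  md <- repair_watertight(read_stl(file.path(dir, "mandible.stl"), "mandible"))
  js <- jsonlite::read_json(file.path(dir, "landmarks.json"))
  lmm <- do.call(rbind, lapply(js$landmarks, function(p) as.numeric(unlist(p))))
  colnames(lmm) <- c("x", "y", "z")
  structure(list(maxilla = mx, mandible = md, landmarks = lmm,
                 preset = js$preset %||% "unknown",
                 seed = as.integer(js$seed %||% NA)),
            class = "anatomy_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
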