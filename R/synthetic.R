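#' Synthetic dentition parameters
#'
#' Geometry controls for [generate_arch()]. Dimensions are millimetres and
#' default to adult full-arch values: 14 crowns (second molar to second molar)
#' on a parabolic arch, sitting in a continuous gingival band with raised
#' interdental papillae. `shape_jitter` scales the per-participant,
#' per-tooth random perturbation of crown dimensions and arch proportions —
#' the individualising anatomy that makes participants distinguishable.
#'
#' @param n_teeth even integer >= 2; number of crowns.
#' @param arch_width outer arch width (mm).
#' @param arch_depth anterior-posterior arch depth (mm).
#' @param crown_height mean crown height (mm).
#' @param crown_width mean mesio-distal crown width (mm).
#' @param gingiva_band_height height of the gingival ridge (mm).
#' @param inter_tooth_gap clearance between adjacent crowns (mm).
#' @param shape_jitter dimensionless perturbation scale (sd as a fraction of
#'   each dimension).
#' @param arch_type `"upper"` or `"lower"`.
#' @return A list of class `dentition_params`.
#' @export
dentition_params <- function(n_teeth = 14L, arch_width = 50, arch_depth = 42,
                             crown_height = 8, crown_width = 6.5,
                             gingiva_band_height = 5, inter_tooth_gap = 0.5,
                             shape_jitter = 0.05,
                             arch_type = c("upper", "lower")) {
  arch_type <- match.arg(arch_type)
  n_teeth <- as.integer(n_teeth)
  if (n_teeth < 2L || n_teeth %% 2L != 0L) stopf("n_teeth must be even and >= 2")
  lens <- c(arch_width = arch_width, arch_depth = arch_depth,
            crown_height = crown_height, crown_width = crown_width,
            gingiva_band_height = gingiva_band_height)
  bad <- names(lens)[!vapply(lens, function(x) is_scalar_number(x) && x > 0, TRUE)]
  if (length(bad)) stopf("parameters must be positive lengths: %s",
                         paste(bad, collapse = ", "))
  if (inter_tooth_gap < 0) stopf("inter_tooth_gap must be >= 0")
  if (shape_jitter < 0) stopf("shape_jitter must be >= 0")
  structure(list(n_teeth = n_teeth, arch_width = arch_width,
                 arch_depth = arch_depth, crown_height = crown_height,
                 crown_width = crown_width,
                 gingiva_band_height = gingiva_band_height,
                 inter_tooth_gap = inter_tooth_gap, shape_jitter = shape_jitter,
                 arch_type = arch_type),
            class = "dentition_params")
}

#' Postmortem degradation parameters
#'
#' Controls for [degrade_to_pm()], emulating how a cast-derived PM scan
#' differs from the direct AM scan of the same dentition: i.i.d. surface
#' noise, a smooth low-frequency deformation (impression/cast distortion),
#' extra noise on gingiva (soft tissue is less consistent than dental hard
#' tissue — the premise that makes segmentation help), an arbitrary rigid
#' placement, and optional vertex decimation.
#'
#' @param noise_sd i.i.d. per-vertex noise sd (mm).
#' @param deform_amplitude maximum smooth-deformation displacement (mm).
#' @param deform_wavelength characteristic wavelength of the deformation (mm).
#' @param rigid_offset a [rigid_transform()] applied to the PM scan, or
#'   `"random"` (rotation <= 30 deg, translation <= 20 mm).
#' @param gingiva_extra_sd additional noise sd on GINGIVA vertices (mm).
#' @param resample_fraction fraction of vertices retained (faces touching
#'   dropped vertices are removed); 1 keeps the mesh intact.
#' @return A list of class `degradation_params`.
#' @export
degradation_params <- function(noise_sd = 0.05, deform_amplitude = 0.2,
                               deform_wavelength = 40, rigid_offset = "random",
                               gingiva_extra_sd = 0.1, resample_fraction = 1) {
  if (noise_sd < 0 || gingiva_extra_sd < 0) stopf("noise sds must be >= 0")
  if (deform_amplitude < 0) stopf("deform_amplitude must be >= 0")
  if (deform_wavelength <= 0) stopf("deform_wavelength must be > 0")
  if (resample_fraction <= 0 || resample_fraction > 1)
    stopf("resample_fraction must lie in (0, 1]")
  if (!identical(rigid_offset, "random") &&
      !inherits(rigid_offset, "rigid_transform"))
    stopf("rigid_offset must be \"random\" or a rigid_transform")
  structure(list(noise_sd = noise_sd, deform_amplitude = deform_amplitude,
                 deform_wavelength = deform_wavelength,
                 rigid_offset = rigid_offset,
                 gingiva_extra_sd = gingiva_extra_sd,
                 resample_fraction = resample_fraction),
            class = "degradation_params")
}

# FDI two-digit codes ordered along the arch from the patient's right distal
# end to the left distal end. 14 teeth on an upper arch: 17..11, 21..27.
fdi_ids <- function(n_teeth, arch_type) {
  k <- n_teeth / 2
  qr <- if (arch_type == "upper") 1L else 4L  # patient right quadrant
  ql <- if (arch_type == "upper") 2L else 3L
  c(sprintf("%d%d", qr, k:1), sprintf("%d%d", ql, 1:k))
}

# Signed power, the superellipsoid building block.
spow <- function(x, e) sign(x) * abs(x)^e

# Superellipsoid crown mesh in local coordinates; semi-axes (a, b, c) along
# (mesio-distal, bucco-lingual, occlusal) with roundness exponents e1 (polar)
# and e2 (equatorial). Returns vertices and faces (u x v grid, v wraps).
superellipsoid <- function(a, b, c_, e1, e2, nu = 13L, nv = 20L) {
  u <- seq(-pi / 2, pi / 2, length.out = nu)
  v <- seq(-pi, pi, length.out = nv + 1L)[seq_len(nv)]
  # snap the trig values at poles/axes exactly to zero before applying the
  # signed power, so coincident grid points are exact duplicates that weld
  snap <- function(x) {
    x[abs(x) < 1e-9] <- 0
    x
  }
  cu <- spow(snap(cos(u)), e1)
  su <- spow(snap(sin(u)), e1)
  cv <- spow(snap(cos(v)), e2)
  sv <- spow(snap(sin(v)), e2)
  x <- a * outer(cu, cv)
  y <- b * outer(cu, sv)
  z <- c_ * matrix(su, nu, nv)
  verts <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))  # column-major: u fastest
  idx <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), nv)
  j <- rep(seq_len(nv), each = nu - 1L)
  jn <- j %% nv + 1L
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
  f2 <- cbind(idx(i, j), idx(i + 1L, jn), idx(i, jn))
  list(vertices = verts, faces = rbind(f1, f2))
}

# Drop zero-area faces (grid poles produce degenerate triangles).
drop_degenerate_faces <- function(verts, faces, tol = 1e-12) {
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  cc <- verts[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  keep <- sqrt(rowSums(cr^2)) > tol
  faces[keep, , drop = FALSE]
}

#' Generate a labelled synthetic dental arch
#'
#' Builds a triangle mesh of `n_teeth` superellipsoid crowns placed along a
#' parabolic arch curve, embedded in a continuous gingival band with raised
#' interdental papillae between adjacent crowns. Tooth vertices carry FDI
#' identifiers; gingiva vertices are labelled `GINGIVA`. All randomness
#' (per-participant arch proportions, per-tooth crown dimensions and
#' roundness) is driven by `participant_seed`, so a participant's anatomy is
#' reproducible. Occlusal is +z; the arch lies in the xy plane, units mm.
#'
#' @param params a [dentition_params()] object.
#' @param participant_seed integer seed identifying the participant (and arch).
#' @return A [labeled_mesh()].
#' @examples
#' arch <- generate_arch(dentition_params(), participant_seed = 11L)
#' length(unique(arch$tooth_id[!is.na(arch$tooth_id)]))  # 14
#' @export
generate_arch <- function(params = dentition_params(), participant_seed = 1L) {
  stopifnot(inherits(params, "dentition_params"))
  with_seed(participant_seed, generate_arch_impl(params))
}

generate_arch_impl <- function(p) {
  jit <- function(n = 1L) pmax(pmin(rnorm(n), 2.5), -2.5) * p$shape_jitter
  # participant-level overall size: tooth and arch dimensions covary (large
  # dentitions sit in large arches), with smaller independent arch-form jitter
  size_fac <- 1 + jit()
  aw <- p$arch_width * size_fac * (1 + 0.5 * jit())
  ad <- p$arch_depth * size_fac * (1 + 0.5 * jit())
  # parabolic arch midline: x in [-aw/2, aw/2], y = ad * (1 - (2x/aw)^2)
  tgrid <- seq(-aw / 2, aw / 2, length.out = 4001L)
  ygrid <- ad * (1 - (2 * tgrid / aw)^2)
  seglen <- sqrt(diff(tgrid)^2 + diff(ygrid)^2)
  s_cum <- c(0, cumsum(seglen))
  arc_len <- s_cum[length(s_cum)]
  curve_at <- function(s) {
    x <- approx(s_cum, tgrid, xout = s, rule = 2)$y
    y <- ad * (1 - (2 * x / aw)^2)
    dydx <- -8 * ad * x / aw^2
    tang <- cbind(1, dydx) / sqrt(1 + dydx^2)
    list(pos = cbind(x, y), tangent = tang, normal = cbind(-tang[, 2], tang[, 1]))
  }

  # crown widths: anatomical scaling from midline (incisors narrow, molars
  # wide), then per-tooth jitter
  k <- p$n_teeth / 2
  half_fac <- c(0.72, 0.80, 0.90, 0.95, 0.95, 1.15, 1.10)
  half_fac <- if (k <= 7) half_fac[seq_len(k)] else c(half_fac, rep(1, k - 7))
  wfac <- c(rev(half_fac), half_fac)  # distal right ... midline ... distal left
  widths <- p$crown_width * size_fac * wfac * (1 + jit(p$n_teeth))
  total_needed <- sum(widths) + (p$n_teeth - 1) * p$inter_tooth_gap
  ids <- fdi_ids(p$n_teeth, p$arch_type)
  if (total_needed > arc_len) {
    i <- which.max(widths[-1] + widths[-p$n_teeth])
    stopf("teeth %s and %s overlap: %d crowns need %.1f mm of arch but only %.1f mm is available",
          ids[i], ids[i + 1], p$n_teeth, total_needed, arc_len)
  }
  s0 <- (arc_len - total_needed) / 2
  centers_s <- s0 + cumsum(widths) - widths / 2 +
    (seq_len(p$n_teeth) - 1) * p$inter_tooth_gap

  gh <- p$gingiva_band_height
  embed <- min(1, p$crown_height * 0.15)
  band_w <- p$crown_width * 1.6
  pap_h <- 1.2
  pap_sigma <- 0.9

  vlist <- list()
  flist <- list()
  tislist <- list()
  idlist <- list()
  nv_acc <- 0L
  cinfo <- curve_at(centers_s)
  heights <- p$crown_height * (1 + jit(p$n_teeth))
  depths <- p$crown_width * 0.82 * wfac * (1 + jit(p$n_teeth))
  e1s <- pmax(0.25, 0.5 * (1 + 2 * jit(p$n_teeth)))
  e2s <- pmax(0.25, 0.5 * (1 + 2 * jit(p$n_teeth)))
  lat_off <- jit(p$n_teeth) * p$crown_width * 0.4
  z_off <- jit(p$n_teeth) * p$crown_height * 0.3

  for (i in seq_len(p$n_teeth)) {
    se <- superellipsoid(widths[i] / 2 * 0.92, depths[i] / 2, heights[i] / 2,
                         e1s[i], e2s[i])
    tang <- c(cinfo$tangent[i, ], 0)
    nrm <- c(cinfo$normal[i, ], 0)
    Rl <- cbind(tang, nrm, c(0, 0, 1))
    ctr <- c(cinfo$pos[i, ] + lat_off[i] * cinfo$normal[i, ],
             gh + heights[i] / 2 - embed + z_off[i])
    vv <- sweep(se$vertices %*% t(Rl), 2, -ctr)
    vlist[[length(vlist) + 1L]] <- vv
    flist[[length(flist) + 1L]] <- se$faces + nv_acc
    tislist[[length(tislist) + 1L]] <- rep("TOOTH", nrow(vv))
    idlist[[length(idlist) + 1L]] <- rep(ids[i], nrow(vv))
    nv_acc <- nv_acc + nrow(vv)
  }

  # adjacency check on actual placements (jitter could in principle collide)
  ctrs <- do.call(rbind, lapply(seq_len(p$n_teeth), function(i)
    c(cinfo$pos[i, ], 0)))
  gaps <- sqrt(rowSums((ctrs[-1, , drop = FALSE] -
                          ctrs[-p$n_teeth, , drop = FALSE])^2))
  min_need <- (widths[-1] + widths[-p$n_teeth]) / 2 * 0.92
  if (any(gaps < min_need)) {
    i <- which(gaps < min_need)[1]
    stopf("teeth %s and %s overlap (centre gap %.2f mm < %.2f mm)",
          ids[i], ids[i + 1], gaps[i], min_need[i])
  }

  # gingival band: ridge cross-section with papilla bumps between crowns
  ns <- 240L
  nu <- 9L
  sgrid <- seq(max(0, s0 - band_w / 2), min(arc_len, max(centers_s) +
                                              widths[p$n_teeth] / 2 + band_w / 2),
               length.out = ns)
  ugrid <- seq(-band_w / 2, band_w / 2, length.out = nu)
  mids_s <- (centers_s[-1] + centers_s[-p$n_teeth]) / 2
  cs <- curve_at(sgrid)
  pap <- rep(0, ns)
  for (m in mids_s) pap <- pap + pap_h * exp(-0.5 * ((sgrid - m) / pap_sigma)^2)
  lat <- 1 - (2 * ugrid / band_w)^2
  z_mat <- outer(gh * rep(1, ns), lat) + outer(pap, pmax(lat, 0))
  gx <- outer(cs$pos[, 1], rep(1, nu)) + outer(cs$normal[, 1], ugrid)
  gy <- outer(cs$pos[, 2], rep(1, nu)) + outer(cs$normal[, 2], ugrid)
  gverts <- cbind(as.numeric(gx), as.numeric(gy), as.numeric(z_mat))
  gidx <- function(i, j) (j - 1L) * ns + i
  i <- rep(seq_len(ns - 1L), nu - 1L)
  j <- rep(seq_len(nu - 1L), each = ns - 1L)
  gf <- rbind(cbind(gidx(i, j), gidx(i + 1L, j), gidx(i + 1L, j + 1L)),
              cbind(gidx(i, j), gidx(i + 1L, j + 1L), gidx(i, j + 1L)))

  verts <- rbind(do.call(rbind, vlist), gverts)
  faces <- rbind(do.call(rbind, flist), gf + nv_acc)
  tissue <- c(unlist(tislist), rep("GINGIVA", nrow(gverts)))
  tooth_id <- c(unlist(idlist), rep(NA_character_, nrow(gverts)))
  faces <- drop_degenerate_faces(verts, faces)
  # merge exact duplicate vertices (crown poles) for consistent identity
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, key)
  keep <- !duplicated(uid)
  remap <- cumsum(keep)[uid]
  faces <- matrix(remap[faces], nrow(faces), 3)
  faces <- faces[faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
                   faces[, 2] != faces[, 3], , drop = FALSE]
  labeled_mesh(verts[keep, , drop = FALSE], faces, tissue[keep],
               tooth_id[keep], frame_id = sprintf("%s-arch", p$arch_type))
}

#' Degrade an AM arch into a PM scan
#'
#' Applies, in order: a smooth low-frequency displacement field (sum of three
#' random sinusoidal modes per axis, total amplitude bounded by
#' `deform_amplitude`), i.i.d. vertex noise (`noise_sd`, plus
#' `gingiva_extra_sd` on gingiva), optional vertex decimation, and a rigid
#' placement. Labels are preserved. The returned `truth` transform maps the
#' PM scan back into the AM frame (the inverse of the applied placement).
#'
#' @param am a [labeled_mesh()] AM scan.
#' @param d a [degradation_params()] object.
#' @param seed integer seed.
#' @return A list with elements `mesh` (the PM [labeled_mesh()]) and `truth`
#'   (PM-to-AM [rigid_transform()]).
#' @export
degrade_to_pm <- function(am, d = degradation_params(), seed = 1L) {
  stopifnot(inherits(am, "labeled_mesh"), inherits(d, "degradation_params"))
  if (nrow(am$vertices) == 0) stopf("AM mesh is empty")
  with_seed(seed, {
    v <- am$vertices
    n <- nrow(v)
    if (d$deform_amplitude > 0) {
      disp <- matrix(0, n, 3)
      axis_amp <- d$deform_amplitude / sqrt(3)
      for (k in 1:3) {
        w <- runif(3, 0.2, 1)
        amp <- sign(runif(3, -1, 1)) * w / sum(w) * axis_amp
        for (jmode in 1:3) {
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2))
          lam <- d$deform_wavelength * runif(1, 0.7, 1.3)
          phase <- runif(1, 0, 2 * pi)
          disp[, k] <- disp[, k] +
            amp[jmode] * sin(2 * pi * (v %*% u) / lam + phase)
        }
      }
      v <- v + disp
    }
    sdv <- d$noise_sd + ifelse(am$tissue == "GINGIVA", d$gingiva_extra_sd, 0)
    if (any(sdv > 0)) v <- v + matrix(rnorm(3 * n), n, 3) * sdv
    tissue <- am$tissue
    tooth_id <- am$tooth_id
    faces <- am$faces
    if (d$resample_fraction < 1) {
      keep <- sort(sample.int(n, max(3L, round(d$resample_fraction * n))))
      remap <- rep(NA_integer_, n)
      remap[keep] <- seq_along(keep)
      fkeep <- faces[rowSums(matrix(faces %in% keep, nrow(faces), 3)) == 3L, ,
                     drop = FALSE]
      faces <- matrix(remap[fkeep], nrow(fkeep), 3)
      v <- v[keep, , drop = FALSE]
      tissue <- tissue[keep]
      tooth_id <- tooth_id[keep]
    }
    placement <- if (identical(d$rigid_offset, "random")) {
      random_transform(30, 20, seed = stable_seed("placement", seed))
    } else {
      d$rigid_offset
    }
    v <- transform_points(placement, v)
    list(mesh = labeled_mesh(v, faces, tissue, tooth_id,
                             frame_id = paste0(am$frame_id, "-pm")),
         truth = invert_transform(placement))
  })
}

#' Generate an AM/PM scan cohort
#'
#' For each participant, generates an upper and a lower arch; the arch itself
#' is the AM (direct) scan, and [degrade_to_pm()] produces the PM (cast) scan
#' with its ground-truth placement. Six participants yield 24 scans.
#'
#' @param n_participants integer >= 2 (below 2 no non-matching pairs exist).
#' @param dp a [dentition_params()] template (arch_type is set per arch).
#' @param deg a [degradation_params()] object.
#' @param seed integer master seed; every scan's randomness derives from it.
#' @return A list of class `dental_cohort`; each element has fields
#'   `participant_id`, `arch`, `capture` (`"AM"`/`"PM"`), `mesh`, and
#'   `truth_transform` (PM-to-AM; identity for AM scans).
#' @examples
#' coh <- make_cohort(2, seed = 7L)
#' length(coh)  # 8 scans
#' @export
make_cohort <- function(n_participants = 6L, dp = dentition_params(),
                        deg = degradation_params(), seed = 1L) {
  if (n_participants < 2) stopf("need at least 2 participants for non-matching pairs")
  scans <- list()
  for (pid in seq_len(n_participants)) {
    for (arch in c("upper", "lower")) {
      p_arch <- dp
      p_arch$arch_type <- arch
      am_seed <- stable_seed("arch", seed, pid, arch)
      am <- generate_arch(p_arch, participant_seed = am_seed)
      am$frame_id <- sprintf("p%d-%s-AM", pid, arch)
      pm <- degrade_to_pm(am, deg, seed = stable_seed("degrade", seed, pid, arch))
      pm$mesh$frame_id <- sprintf("p%d-%s-PM", pid, arch)
      scans[[length(scans) + 1L]] <-
        list(participant_id = pid, arch = arch, capture = "AM", mesh = am,
             truth_transform = identity_transform())
      scans[[length(scans) + 1L]] <-
        list(participant_id = pid, arch = arch, capture = "PM", mesh = pm$mesh,
             truth_transform = pm$truth)
    }
  }
  structure(scans, class = "dental_cohort",
            n_participants = as.integer(n_participants), seed = as.integer(seed))
}

#' @export
print.dental_cohort <- function(x, ...) {
  cat(sprintf("dental_cohort: %d participants, %d scans\n",
              attr(x, "n_participants"), length(x)))
  invisible(x)
}

# Retrieve one scan from a cohort.
cohort_scan <- function(cohort, participant_id, arch, capture) {
  for (s in cohort) {
    if (s$participant_id == participant_id && s$arch == arch &&
        s$capture == capture) return(s)
  }
  stopf("no %s %s scan for participant %s", capture, arch, participant_id)
}

#' Write a cohort to disk
#'
#' Writes each scan as STL (+ label sidecar) and a manifest CSV with the
#' ground-truth PM-to-AM transform flattened row-major (12 numbers).
#'
#' @param cohort a `dental_cohort`.
#' @param dir output directory (created if needed).
#' @param dialect STL dialect passed to [write_stl()].
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, dialect = "binary") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    stem <- sprintf("p%02d_%s_%s", s$participant_id, s$arch, s$capture)
    stl <- file.path(dir, paste0(stem, ".stl"))
    write_stl(s$mesh, stl, dialect = dialect)
    tfm <- as_matrix4(s$truth_transform)[1:3, ]
    cbind(data.frame(participant_id = s$participant_id, arch = s$arch,
                     capture = s$capture, stl_path = basename(stl),
                     label_path = basename(sidecar_path(stl)),
                     stringsAsFactors = FALSE),
          as.data.frame(t(setNames(as.numeric(t(tfm)),
                                   paste0("t", 1:12)))))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
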