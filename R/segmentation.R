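#' Oriented clipping plane
#'
#' The plane `{p : normal . p = offset}`; the kept side of a slice is the set
#' of points with signed distance `normal . p - offset >= 0`. The normal is
#' oriented occlusally (toward the biting surfaces), so the kept side retains
#' the crowns.
#'
#' @param normal length-3 vector (normalised internally; must be non-zero).
#' @param offset scalar offset (mm).
#' @return An object of class `plane`.
#' @export
plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm == 0) stopf("plane normal must be non-zero")
  structure(list(normal = normal / nrm, offset = as.numeric(offset) / nrm),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("plane: normal (%.4f, %.4f, %.4f), offset %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

# Signed distances of cloud points to a plane.
signed_distance <- function(cloud, pl) {
  as.numeric(cloud$points %*% pl$normal) - pl$offset
}

#' Segmentation methods
#'
#' The five strategies compared by the identification pipeline:
#' * `M1_NONE` — no segmentation (control).
#' * `M2_SEMI_AUTO_GINGIVAL` — gingival reduction retaining a collar of
#'   gingiva (`margin_offset`) above the margin, per image, before
#'   registration.
#' * `M3_MANUAL_GINGIVAL` — full gingival reduction to tooth surfaces only,
#'   per image, before registration.
#' * `M4_PLANAR` — an individual planar slice per image, in each image's own
#'   frame, before registration.
#' * `M5_JOINT_PLANAR` — the joint method: initial registration of the
#'   untrimmed images, then a single plane fitted to the superimposed pair
#'   and applied to both, followed by secondary registration.
#'
#' @return Character vector of the five method codes.
#' @export
segmentation_methods <- function() {
  c("M1_NONE", "M2_SEMI_AUTO_GINGIVAL", "M3_MANUAL_GINGIVAL", "M4_PLANAR",
    "M5_JOINT_PLANAR")
}

#' Segmentation parameters
#'
#' @param margin_offset mm of gingival collar retained above the tooth margin
#'   by the semi-automatic reduction (M2). `0` reproduces the manual mode.
#' @param plane_drop mm the slicing plane is lowered from the mean
#'   tooth-gingiva boundary height toward the gingiva (M4/M5); the default 0
#'   keeps interdental papillae above the cut.
#' @param plane_jitter_sd operator-variability model for plane placement:
#'   sd of the random plane offset (mm) and of the random normal tilt
#'   (degrees). A scalar is used for both; a length-2 vector gives
#'   `c(mm, degrees)`.
#' @param seed integer seed for the jitter stream.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(margin_offset = 0.5, plane_drop = 0,
                                plane_jitter_sd = 0, seed = 1L) {
  if (margin_offset < 0) stopf("margin_offset must be >= 0")
  if (length(plane_jitter_sd) == 1L) plane_jitter_sd <- rep(plane_jitter_sd, 2)
  if (any(plane_jitter_sd < 0)) stopf("plane_jitter_sd must be >= 0")
  structure(list(margin_offset = margin_offset, plane_drop = plane_drop,
                 plane_jitter_sd = as.numeric(plane_jitter_sd),
                 seed = as.integer(seed)),
            class = "segmentation_params")
}

#' Planar slice of a point cloud
#'
#' Retains exactly the points on the kept side of the plane (signed distance
#' `>= 0`; boundary points are retained). Labels are carried along and the
#' point order is preserved. The indices of retained points are attached as
#' attribute `"index"`.
#'
#' @param cloud a [point_cloud()].
#' @param pl a [plane()].
#' @return The clipped [point_cloud()].
#' @export
plane_slice <- function(cloud, pl) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(pl, "plane"))
  keep <- which(signed_distance(cloud, pl) >= 0)
  out <- subset_cloud(cloud, keep)
  if (length(keep) == 0)
    message("plane_slice: empty result (plane removed every point)")
  attr(out, "index") <- keep
  out
}

#' Fit a slicing plane to an arch cloud
#'
#' Fits the least-squares plane of the cloud (smallest principal component),
#' orients the normal toward the occlusal side — the side holding the greater
#' mass of TOOTH-labelled points, or for unlabelled clouds the side the
#' height distribution is skewed toward (crowns protrude) — and places the
#' offset at the mean tooth-gingiva boundary height minus `plane_drop`.
#' The boundary height is estimated as the midpoint between the lower tail of
#' the tooth heights and the upper tail of the gingiva heights along the
#' normal; for unlabelled clouds the upper-quartile height is used. Optional
#' seeded jitter of the offset (mm) and normal tilt (degrees) models operator
#' variability in landmark selection.
#'
#' @param cloud a [point_cloud()] with at least 3 points.
#' @param params a [segmentation_params()] object.
#' @param seed seed for the jitter stream (defaults to `params$seed`).
#' @return A [plane()].
#' @export
fit_slicing_plane <- function(cloud, params = segmentation_params(),
                              seed = params$seed) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  if (nrow(pts) < 3) stopf("need at least 3 points to fit a plane")
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  nrml <- ev$vectors[, 3]
  h <- as.numeric(pts %*% nrml)
  labelled <- !is.null(cloud$tissue) && any(cloud$tissue == "TOOTH")
  if (labelled) {
    ht <- h[cloud$tissue == "TOOTH"]
    if (mean(ht) < mean(h)) {
      nrml <- -nrml
      h <- -h
      ht <- -ht
    }
    hg <- h[cloud$tissue != "TOOTH"]
    boundary <- if (length(hg)) {
      (quantile(ht, 0.05, names = FALSE) + quantile(hg, 0.95, names = FALSE)) / 2
    } else {
      quantile(ht, 0.05, names = FALSE)
    }
  } else {
    med <- stats::median(h)
    if (mean((h - med)^3) < 0) {
      nrml <- -nrml
      h <- -h
    }
    boundary <- quantile(h, 0.75, names = FALSE)
  }
  offset <- boundary - params$plane_drop
  if (any(params$plane_jitter_sd > 0)) {
    with_seed(seed, {
      tilt <- rnorm(1, 0, params$plane_jitter_sd[2])
      ax <- rnorm(3)
      ax <- ax - sum(ax * nrml) * nrml  # tilt axis within the plane
      if (sqrt(sum(ax^2)) > 0 && abs(tilt) > 0) {
        ctr_h <- mean(h)
        nrml2 <- as.numeric(rotation_about(ax, tilt) %*% nrml)
        # keep the plane passing through the same centre height
        ctr_pt <- colMeans(pts) + (offset - ctr_h) * nrml
        offset <- sum(ctr_pt * nrml2)
        nrml <- nrml2
      }
      offset <- offset + rnorm(1, 0, params$plane_jitter_sd[1])
    })
  }
  plane(nrml, offset)
}

#' Gingival reduction of a labelled cloud
#'
#' Manual mode retains exactly the TOOTH-labelled points (precise removal
#' along the gingival margins into the interdental spaces). Semi-automatic
#' mode additionally retains GINGIVA points within `margin_offset` mm of any
#' TOOTH point — a collar along the margin; the two modes differ only in the
#' extent of soft-tissue removal, and `margin_offset = 0` makes them
#' coincide.
#'
#' @param cloud a [point_cloud()] carrying tissue labels.
#' @param mode `"manual"` or `"semi_auto"`.
#' @param params a [segmentation_params()] (supplies `margin_offset`).
#' @return The reduced [point_cloud()], retained indices in attribute
#'   `"index"`.
#' @export
gingival_reduction <- function(cloud, mode = c("manual", "semi_auto"),
                               params = segmentation_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$tissue))
    stopf("gingival reduction needs tissue labels; use the planar methods (M4/M5) for unlabelled clouds")
  tooth <- which(cloud$tissue == "TOOTH")
  keep <- tooth
  if (mode == "semi_auto" && params$margin_offset > 0 && length(tooth)) {
    ging <- which(cloud$tissue == "GINGIVA")
    if (length(ging)) {
      nn <- .nn_kdtree(cloud$points[tooth, , drop = FALSE],
                       cloud$points[ging, , drop = FALSE])
      keep <- sort(c(tooth, ging[nn$distance <= params$margin_offset]))
    }
  }
  out <- subset_cloud(cloud, keep)
  attr(out, "index") <- keep
  out
}

#' Segment an AM/PM pair
#'
#' Applies one of the five strategies to a pair of clouds:
#' * M1 returns the inputs unchanged.
#' * M2/M3 apply [gingival_reduction()] to each cloud independently.
#' * M4 fits and applies a slicing plane to each cloud independently, in each
#'   cloud's own frame (jitter streams differ between the two images,
#'   mirroring two independent operator actions).
#' * M5 first registers PM onto AM ([icp_register()] on the full clouds),
#'   maps PM into the AM frame, fits one plane to the union of the
#'   superimposed clouds, slices both with that single plane, and returns the
#'   PM cloud restored to its native frame together with the recorded initial
#'   transform and plane.
#'
#' @param am,pm [point_cloud()]s (labelled for M2/M3).
#' @param method one of [segmentation_methods()].
#' @param sp a [segmentation_params()] object.
#' @param icp an [icp_params()] object (used by M5's initial registration).
#' @return A list of class `segmented_pair`: `am_segmented`, `pm_segmented`,
#'   `method`, `initial_transform` (M5 only), `plane_used` (M4: list of the
#'   two planes; M5: the joint plane, in the AM frame), and the retained
#'   index vectors `am_index`, `pm_index`.
#' @export
segment_pair <- function(am, pm, method, sp = segmentation_params(),
                         icp = icp_params()) {
  method <- match.arg(method, segmentation_methods())
  init <- NULL
  pl_used <- NULL
  if (method == "M1_NONE") {
    am_seg <- am
    pm_seg <- pm
    ai <- seq_len(n_points(am))
    pi_ <- seq_len(n_points(pm))
  } else if (method %in% c("M2_SEMI_AUTO_GINGIVAL", "M3_MANUAL_GINGIVAL")) {
    mode <- if (method == "M2_SEMI_AUTO_GINGIVAL") "semi_auto" else "manual"
    am_seg <- gingival_reduction(am, mode, sp)
    pm_seg <- gingival_reduction(pm, mode, sp)
    ai <- attr(am_seg, "index")
    pi_ <- attr(pm_seg, "index")
  } else if (method == "M4_PLANAR") {
    pl_am <- fit_slicing_plane(am, sp, seed = sp$seed)
    pl_pm <- fit_slicing_plane(pm, sp, seed = sp$seed + 1L)
    am_seg <- plane_slice(am, pl_am)
    pm_seg <- plane_slice(pm, pl_pm)
    ai <- attr(am_seg, "index")
    pi_ <- attr(pm_seg, "index")
    pl_used <- list(am = pl_am, pm = pl_pm)
  } else {  # M5_JOINT_PLANAR
    icp0 <- icp_register(pm, am, icp)
    init <- icp0$transform
    pm_in_am <- transform_cloud(init, pm, frame_id = am$frame_id)
    union_cloud <- point_cloud(rbind(am$points, pm_in_am$points),
                               tissue = if (is.null(am$tissue) ||
                                            is.null(pm$tissue)) NULL else
                                 c(am$tissue, pm$tissue),
                               frame_id = am$frame_id)
    pl_used <- fit_slicing_plane(union_cloud, sp, seed = sp$seed)
    am_seg <- plane_slice(am, pl_used)
    pm_seg_am <- plane_slice(pm_in_am, pl_used)
    pi_ <- attr(pm_seg_am, "index")
    pm_seg <- subset_cloud(pm, pi_)  # native PM frame
    ai <- attr(am_seg, "index")
  }
  structure(list(am_segmented = am_seg, pm_segmented = pm_seg, method = method,
                 initial_transform = init, plane_used = pl_used,
                 am_index = ai, pm_index = pi_),
            class = "segmented_pair")
}

#' Compare an AM/PM pair under one segmentation method
#'
#' Runs [segment_pair()] and then the final registration
#' `icp_register(pm_segmented, am_segmented)` — for the joint planar method
#' the secondary registration is warm-started from the stored initial
#' transform, mirroring the sequential workflow. Records the final RMS.
#'
#' @inheritParams segment_pair
#' @return A list of class `comparison_result`: `method`, `rms` (mm),
#'   `icp` (the final `icp_result`), `segmented` (the `segmented_pair`).
#' @export
compare_pair <- function(am, pm, method, sp = segmentation_params(),
                         icp = icp_params()) {
  seg <- segment_pair(am, pm, method, sp, icp)
  res <- icp_register(seg$pm_segmented, seg$am_segmented, icp,
                      init = seg$initial_transform)
  structure(list(method = seg$method, rms = res$rms, icp = res,
                 segmented = seg),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: final RMS %.4f mm (%d iterations)\n", x$method, x$rms,
              x$icp$iterations))
  invisible(x)
}

#' Serialize / read a plane as JSON
#'
#' @param pl a [plane()].
#' @param path file path.
#' @return `read_plane` returns a [plane()]; `write_plane` invisibly `path`.
#' @export
write_plane <- function(pl, path) {
  jsonlite::write_json(list(normal = pl$normal, offset = pl$offset), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  x <- jsonlite::fromJSON(path)
  plane(x$normal, x$offset)
}
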