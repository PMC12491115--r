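#' ICP parameters
#'
#' Controls for [icp_register()]. Registration is trimmed point-to-point ICP:
#' at each iteration the `trim_fraction` worst correspondences are discarded
#' before the rigid update, bounding the influence of non-overlapping capture
#' extent between AM and PM scans. `trim_fraction = 0` reproduces classical
#' ICP. Convergence is on the relative change of the trimmed RMS, so the
#' criterion is scale-robust.
#'
#' @param max_iterations iteration cap.
#' @param rel_tolerance relative trimmed-RMS change below which ICP stops.
#' @param trim_fraction fraction in `[0, 0.5]` of worst correspondences
#'   discarded per iteration.
#' @param sample_size source/target points used (larger clouds are subsampled
#'   without replacement, seeded); reported RMS refers to the subsample.
#' @param seed integer seed for subsampling.
#' @param pre_align `"centroid_pca"` (deterministic centroid + principal-axes
#'   pre-alignment, sign-disambiguated by initial RMS) or `"identity"`.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, rel_tolerance = 1e-6,
                       trim_fraction = 0.1, sample_size = 20000L, seed = 1L,
                       pre_align = c("centroid_pca", "identity")) {
  pre_align <- match.arg(pre_align)
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (rel_tolerance < 0) stopf("rel_tolerance must be >= 0")
  if (trim_fraction < 0 || trim_fraction > 0.5)
    stopf("trim_fraction must lie in [0, 0.5]")
  if (sample_size < 3) stopf("sample_size must be >= 3")
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tolerance = rel_tolerance, trim_fraction = trim_fraction,
                 sample_size = as.integer(sample_size), seed = as.integer(seed),
                 pre_align = pre_align),
            class = "icp_params")
}

#' Least-squares rigid fit of paired points
#'
#' Given matched source and target points, returns the rigid transform
#' minimising the sum of squared paired distances (Kabsch/SVD solution, with
#' the reflection corrected through the sign of the smallest singular vector
#' so the rotation is always proper).
#'
#' @param source,target `n x 3` matrices or [point_cloud()]s with equal
#'   counts, `n >= 3`, not all collinear.
#' @return A [rigid_transform()] mapping source onto target.
#' @export
estimate_rigid <- function(source, target) {
  S <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  T_ <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(S) != nrow(T_)) stopf("paired point sets must have equal counts")
  if (nrow(S) < 3) stopf("need at least 3 paired points")
  cs <- colMeans(S)
  ct <- colMeans(T_)
  Sc <- sweep(S, 2, cs)
  Tc <- sweep(T_, 2, ct)
  H <- crossprod(Sc, Tc)
  sv <- svd(H)
  scale_ref <- max(sqrt(mean(rowSums(Sc^2))), sqrt(mean(rowSums(Tc^2))))
  if (scale_ref == 0 || sv$d[2] < 1e-12 * max(sv$d[1], scale_ref^2))
    stopf("degenerate point configuration (collinear or coincident points)")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Nearest neighbours between two clouds
#'
#' For every source point, the index and Euclidean distance (mm) of its
#' closest target point, via a kd-tree. Distance ties resolve to the lowest
#' target index.
#'
#' @param source,target [point_cloud()]s or `n x 3` matrices; target non-empty.
#' @return A list with `index` (1-based into target) and `distance` (mm).
#' @export
nearest_neighbors <- function(source, target) {
  S <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  T_ <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(T_) == 0) stopf("target cloud is empty")
  .nn_kdtree(T_, S)
}

#' Root mean square of distances
#'
#' @param distances non-empty numeric vector of distances (mm).
#' @return `sqrt(mean(distances^2))` in mm.
#' @export
rms_of_distances <- function(distances) {
  if (length(distances) == 0) stopf("cannot take RMS of zero distances")
  sqrt(mean(distances^2))
}

# Deterministic centroid + principal-axes pre-alignment. Among the four
# proper-rotation sign combinations of the matched principal axes, the one
# with the lowest initial nearest-neighbour RMS wins.
pre_align_pca <- function(S, T_) {
  cs <- colMeans(S)
  ct <- colMeans(T_)
  es <- eigen(stats::cov(S), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(T_), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_rms <- Inf
  for (sg in signs) {
    R <- et %*% diag(sg) %*% t(es)
    tf <- rigid_transform(R, ct - as.numeric(R %*% cs))
    d <- .nn_kdtree(T_, transform_points(tf, S))$distance
    r <- rms_of_distances(d)
    if (r < best_rms) {
      best_rms <- r
      best <- tf
    }
  }
  best
}

#' Trimmed ICP registration
#'
#' Registers `source` onto `target` by iterating nearest-neighbour
#' correspondence, trimming of the worst pairs, and a least-squares rigid
#' update, until the trimmed RMS stops improving. The reported RMS is the
#' one-directional source-to-target RMS over the retained correspondences of
#' the final iteration (by convention PM-to-AM in the identification
#' pipeline; RMS is not symmetric for partially overlapping clouds).
#'
#' @param source,target [point_cloud()]s with at least 3 points each.
#' @param params an [icp_params()] object.
#' @param init optional [rigid_transform()] warm start overriding
#'   `params$pre_align` (used by the joint planar method's secondary
#'   registration).
#' @return A list of class `icp_result`: `transform` (source to target),
#'   `rms` (mm), `rms_history`, `iterations`, `converged`,
#'   `n_correspondences`.
#' @examples
#' pts <- matrix(rnorm(300), ncol = 3)
#' tf <- rigid_transform(rotation_about(c(0, 0, 1), 10), c(1, 2, 3))
#' res <- icp_register(point_cloud(pts), point_cloud(transform_points(tf, pts)),
#'                     icp_params(trim_fraction = 0))
#' res$rms
#' @export
icp_register <- function(source, target, params = icp_params(), init = NULL) {
  stopifnot(inherits(params, "icp_params"))
  S <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  T_ <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(S) < 3 || nrow(T_) < 3) stopf("both clouds need at least 3 points")
  S <- subsample_rows(S, params$sample_size, params$seed)
  T_ <- subsample_rows(T_, params$sample_size, params$seed + 1L)

  tf <- if (!is.null(init)) {
    stopifnot(inherits(init, "rigid_transform"))
    init
  } else if (params$pre_align == "centroid_pca") {
    pre_align_pca(S, T_)
  } else {
    identity_transform()
  }

  n <- nrow(S)
  keep_n <- max(3L, as.integer(ceiling((1 - params$trim_fraction) * n)))
  history <- numeric(0)
  converged <- FALSE
  rms <- NA_real_
  it <- 0L
  P <- transform_points(tf, S)
  for (it in seq_len(params$max_iterations)) {
    nn <- .nn_kdtree(T_, P)
    ord <- order(nn$distance)[seq_len(keep_n)]
    if (length(ord) < 3) stopf("fewer than 3 correspondences retained after trimming")
    upd <- estimate_rigid(P[ord, , drop = FALSE],
                          T_[nn$index[ord], , drop = FALSE])
    tf <- compose_transforms(upd, tf)
    P <- transform_points(upd, P)
    d_new <- sqrt(rowSums((P[ord, , drop = FALSE] -
                             T_[nn$index[ord], , drop = FALSE])^2))
    rms <- rms_of_distances(d_new)
    history <- c(history, rms)
    if (it > 1) {
      prev <- history[it - 1]
      if ((prev - rms) / max(prev, .Machine$double.eps) < params$rel_tolerance) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(transform = tf, rms = rms, rms_history = history,
                 iterations = it, converged = converged,
                 n_correspondences = keep_n),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("ICP: rms %.6f mm after %d iterations (%s, %d correspondences)\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "iteration cap", x$n_correspondences))
  invisible(x)
}

subsample_rows <- function(m, k, seed) {
  if (nrow(m) <= k) return(m)
  with_seed(seed, m[sort(sample.int(nrow(m), k)), , drop = FALSE])
}
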