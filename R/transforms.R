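#' Rigid transforms in 3D
#'
#' A `rigid_transform` is a proper rotation plus a translation, mapping points
#' from one scan's coordinate frame into another's: `p' = R p + t`. It is the
#' output of registration and the ground truth carried by the synthetic
#' dentition generator.
#'
#' @param rotation 3x3 orthogonal matrix with determinant +1.
#' @param translation numeric length-3 translation in millimetres.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(rotation_about(c(0, 0, 1), 10), c(1, 2, 3))
#' pts <- matrix(rnorm(30), ncol = 3)
#' max(abs(transform_points(invert_transform(tf), transform_points(tf, pts)) - pts))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stopf("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stopf("rigid_transform components must be finite")
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stopf("rotation is not a proper rotation (orthogonality error %.2e, det %.12f)",
          ortho_err, det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: rotation", sprintf("%.4f deg", rotation_angle(x)),
      "| translation", sprintf("(%.4f, %.4f, %.4f) mm", x$translation[1],
                               x$translation[2], x$translation[3]), "\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Rotation matrix about an axis
#'
#' @param axis numeric length-3 rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stopf("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply, compose and invert rigid transforms
#'
#' `transform_points` maps an `n x 3` matrix of points; `compose_transforms`
#' returns the transform equivalent to applying `b` first and then `a`;
#' `invert_transform` returns the inverse map; `rotation_angle` gives the
#' rotation magnitude in degrees; `as_matrix4` the 4x4 homogeneous matrix
#' (row-major when flattened), the serialization format used on disk.
#'
#' @param transform,a,b `rigid_transform` objects.
#' @param points numeric `n x 3` matrix (mm).
#' @return See each description.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @rdname transform_points
#' @export
rotation_angle <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' @rdname transform_points
#' @export
as_matrix4 <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Draw a random rigid transform
#'
#' Rotation axis uniform on the sphere, angle uniform in `[0, max_angle_deg]`,
#' translation uniform in the ball of radius `max_translation_mm`. Used by the
#' synthetic generator to emulate arbitrary scan placement.
#'
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation_mm maximum translation norm (mm).
#' @param seed integer seed.
#' @return A `rigid_transform`.
#' @export
random_transform <- function(max_angle_deg = 30, max_translation_mm = 20,
                             seed = 1L) {
  with_seed(seed, {
    ax <- rnorm(3)
    ang <- runif(1, 0, max_angle_deg)
    tr <- rnorm(3)
    tr <- tr / sqrt(sum(tr^2)) * max_translation_mm * runif(1)^(1 / 3)
    rigid_transform(rotation_about(ax, ang), tr)
  })
}
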