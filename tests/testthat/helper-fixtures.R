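# Shared fixtures, all built in code.

# One right triangle in the z = 0 plane.
one_triangle_mesh <- function() {
  labeled_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               matrix(c(1L, 2L, 3L), 1))
}

# Two coplanar triangles with areas 1 and 3 (legs sqrt(2) and sqrt(6)).
two_triangle_mesh <- function() {
  s <- sqrt(2)
  t <- sqrt(6)
  labeled_mesh(rbind(c(0, 0, 0), c(s, 0, 0), c(0, s, 0),
                     c(10, 0, 0), c(10 + t, 0, 0), c(10, t, 0)),
               rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
}

# A small arch that is cheap to build but exercises every code path.
small_arch <- function(seed = 5L, arch_type = "upper") {
  generate_arch(dentition_params(n_teeth = 6L, arch_width = 30, arch_depth = 26,
                                 arch_type = arch_type),
                participant_seed = seed)
}

# Labelled cloud with a simple known structure: gingiva sheet at z = 0,
# tooth block points above.
stub_labeled_cloud <- function(n_ging = 300L, n_tooth = 200L, seed = 2L) {
  with_seed(seed, {
    g <- cbind(runif(n_ging, -10, 10), runif(n_ging, -10, 10), 0)
    t_ <- cbind(runif(n_tooth, -6, 6), runif(n_tooth, -6, 6), runif(n_tooth, 2, 8))
    point_cloud(rbind(g, t_),
                tissue = c(rep("GINGIVA", n_ging), rep("TOOTH", n_tooth)))
  })
}

# Scan lookup over a cohort list.
cohort_scan_public <- function(cohort, pid, arch, capture) {
  for (s in cohort) {
    if (s$participant_id == pid && s$arch == arch && s$capture == capture)
      return(s)
  }
  stop("scan not found")
}

# Point-in-triangle membership by barycentric coordinates (brute force).
point_in_face <- function(p, a, b, c_, tol = 1e-9) {
  v0 <- b - a
  v1 <- c_ - a
  v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  # in-plane residual
  nrm <- c(v0[2] * v1[3] - v0[3] * v1[2], v0[3] * v1[1] - v0[1] * v1[3],
           v0[1] * v1[2] - v0[2] * v1[1])
  off <- abs(sum(v2 * nrm)) / sqrt(sum(nrm^2))
  off < tol && u >= -tol && v >= -tol && w >= -tol
}
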