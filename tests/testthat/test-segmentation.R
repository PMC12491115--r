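test_that("plane_slice retains exactly the non-negative side, boundary included", {
  cl <- stub_labeled_cloud()
  pl <- plane(c(0, 0, 1), 1.5)
  out <- plane_slice(cl, pl)
  # brute-force signed-distance oracle
  keep <- which(cl$points %*% c(0, 0, 1) - 1.5 >= 0)
  expect_identical(attr(out, "index"), keep)
  expect_identical(out$points, cl$points[keep, , drop = FALSE])
  # vacuous cut far below
  all_kept <- plane_slice(cl, plane(c(0, 0, 1), -100))
  expect_equal(n_points(all_kept), n_points(cl))
  # a point exactly on the plane is retained
  on_pl <- point_cloud(rbind(c(0, 0, 1.5), c(0, 0, 1.4999)))
  kept <- plane_slice(on_pl, pl)
  expect_identical(attr(kept, "index"), 1L)
})

test_that("fitted slicing plane orients occlusally and is deterministic", {
  # symmetric construction with a known answer: gingiva grid in z = 0,
  # tooth points mirrored in x and y so cross-covariances vanish exactly
  g <- as.matrix(expand.grid(x = seq(-10, 10, by = 1), y = seq(-10, 10, by = 1)))
  g <- cbind(g, 0)
  tpos <- as.matrix(expand.grid(x = c(-4, 4), y = c(-4, 4), z = c(3, 6)))
  sym <- point_cloud(rbind(g, tpos),
                     tissue = c(rep("GINGIVA", nrow(g)), rep("TOOTH", nrow(tpos))))
  pl_sym <- fit_slicing_plane(sym, segmentation_params())
  expect_gt(pl_sym$normal[3], 1 - 1e-6)

  cl <- stub_labeled_cloud()
  pl <- fit_slicing_plane(cl, segmentation_params())
  expect_gt(pl$normal[3], 0.99)  # +z up to sampling tilt, teeth above
  pl2 <- fit_slicing_plane(cl, segmentation_params())
  expect_identical(pl$normal, pl2$normal)
  expect_identical(pl$offset, pl2$offset)
  # the cut keeps all tooth points and removes most of the flat gingiva
  out <- plane_slice(cl, pl)
  expect_true(all(out$tissue[out$points[, 3] > 2] == "TOOTH"))
  expect_lt(mean(cl$tissue[attr(out, "index")] == "GINGIVA"), 0.5)
  expect_error(fit_slicing_plane(point_cloud(rbind(c(0, 0, 0)))), "3 points")
})

test_that("plane jitter perturbs replicate planes", {
  cl <- stub_labeled_cloud()
  sp <- segmentation_params(plane_jitter_sd = c(0.2, 1))
  p1 <- fit_slicing_plane(cl, sp, seed = 1L)
  p2 <- fit_slicing_plane(cl, sp, seed = 2L)
  expect_gt(abs(p1$offset - p2$offset) + sum(abs(p1$normal - p2$normal)), 0)
})

test_that("gingival reduction matches its brute-force distance oracle", {
  cl <- stub_labeled_cloud(n_ging = 300L, n_tooth = 200L)
  sp <- segmentation_params(margin_offset = 1.2)
  semi <- gingival_reduction(cl, "semi_auto", sp)
  manual <- gingival_reduction(cl, "manual", sp)
  tooth_idx <- which(cl$tissue == "TOOTH")
  expect_identical(attr(manual, "index"), tooth_idx)
  # O(n^2) oracle for the collar
  tooth_pts <- cl$points[tooth_idx, , drop = FALSE]
  keep_oracle <- sort(c(tooth_idx, which(vapply(seq_len(n_points(cl)), function(i) {
    cl$tissue[i] == "GINGIVA" &&
      min(sqrt(colSums((t(tooth_pts) - cl$points[i, ])^2))) <= 1.2
  }, logical(1)))))
  expect_identical(attr(semi, "index"), keep_oracle)
  # collar of zero reproduces manual mode
  semi0 <- gingival_reduction(cl, "semi_auto", segmentation_params(margin_offset = 0))
  expect_identical(attr(semi0, "index"), attr(manual, "index"))
  # manual reduction of an all-tooth cloud is the identity
  pure <- subset_cloud(cl, tooth_idx)
  expect_equal(n_points(gingival_reduction(pure, "manual")), length(tooth_idx))
  expect_error(gingival_reduction(point_cloud(cl$points), "manual"), "labels")
})

test_that("segmented point sets nest: manual within semi-auto within input", {
  arch <- small_arch()
  cl <- sample_surface(arch, 1500, seed = 4L)
  m3 <- gingival_reduction(cl, "manual")
  m2 <- gingival_reduction(cl, "semi_auto", segmentation_params(margin_offset = 0.5))
  expect_true(all(attr(m3, "index") %in% attr(m2, "index")))
  expect_lte(n_points(m2), n_points(cl))
})

test_that("method M1 passes clouds through untouched", {
  arch <- small_arch()
  a <- sample_surface(arch, 800, seed = 1L)
  b <- sample_surface(arch, 800, seed = 2L)
  seg <- segment_pair(a, b, "M1_NONE")
  expect_identical(seg$am_segmented$points, a$points)
  expect_identical(seg$pm_segmented$points, b$points)
})

test_that("the joint plane slices a rigid copy into identical point sets", {
  arch <- small_arch(seed = 7L)
  a <- sample_surface(arch, 1200, seed = 3L)
  truth <- random_transform(20, 12, seed = 4L)
  b <- transform_cloud(truth, a)  # PM = exact rigid copy of AM
  seg <- segment_pair(a, b, "M5_JOINT_PLANAR", segmentation_params(),
                      icp_params(sample_size = 1200L, trim_fraction = 0))
  expect_identical(seg$am_index, seg$pm_index)
})

test_that("feeding the joint plane back through individual slicing reproduces M5 subsets", {
  arch <- small_arch(seed = 11L)
  pmres <- degrade_to_pm(arch, degradation_params(), seed = 2L)
  a <- sample_surface(arch, 1200, seed = 5L)
  b <- sample_surface(pmres$mesh, 1200, seed = 5L, template = arch)
  icp <- icp_params(sample_size = 1200L)
  seg5 <- segment_pair(a, b, "M5_JOINT_PLANAR", segmentation_params(), icp)
  # apply M5's plane directly in the common frame, as method 4 would
  b_in_a <- transform_cloud(seg5$initial_transform, b)
  am_direct <- plane_slice(a, seg5$plane_used)
  pm_direct <- plane_slice(b_in_a, seg5$plane_used)
  expect_identical(attr(am_direct, "index"), seg5$am_index)
  expect_identical(attr(pm_direct, "index"), seg5$pm_index)
})

test_that("the joint planar method is invariant to PM frame displacement", {
  arch <- small_arch(seed = 13L)
  pmres <- degrade_to_pm(arch, degradation_params(), seed = 6L)
  a <- sample_surface(arch, 1200, seed = 8L)
  b <- sample_surface(pmres$mesh, 1200, seed = 8L, template = arch)
  icp <- icp_params(sample_size = 1200L)
  r1 <- compare_pair(a, b, "M5_JOINT_PLANAR", segmentation_params(), icp)
  g <- random_transform(25, 18, seed = 41L)
  r2 <- compare_pair(a, transform_cloud(g, b), "M5_JOINT_PLANAR",
                     segmentation_params(), icp)
  expect_identical(r1$segmented$am_index, r2$segmented$am_index)
  expect_identical(r1$segmented$pm_index, r2$segmented$pm_index)
  expect_lt(abs(r1$rms - r2$rms), 1e-6)
})

test_that("an untransformed copy compares at numerically zero RMS under every method", {
  arch <- small_arch(seed = 15L)
  a <- sample_surface(arch, 1000, seed = 2L)
  icp <- icp_params(sample_size = 1000L)
  for (m in segmentation_methods()) {
    r <- compare_pair(a, a, m, segmentation_params(), icp)
    expect_lte(r$rms, 1e-9)
  }
})

test_that("comparisons are bit-stable across reruns with fixed seeds", {
  arch <- small_arch(seed = 16L)
  pmres <- degrade_to_pm(arch, degradation_params(), seed = 1L)
  a <- sample_surface(arch, 900, seed = 1L)
  b <- sample_surface(pmres$mesh, 900, seed = 1L, template = arch)
  icp <- icp_params(sample_size = 900L)
  sp <- segmentation_params(plane_jitter_sd = c(0.2, 1), seed = 5L)
  for (m in c("M2_SEMI_AUTO_GINGIVAL", "M4_PLANAR", "M5_JOINT_PLANAR")) {
    expect_identical(compare_pair(a, b, m, sp, icp)$rms,
                     compare_pair(a, b, m, sp, icp)$rms)
  }
})

test_that("plane serialization round-trips through JSON", {
  pl <- plane(c(0.1, -0.2, 0.97), 3.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_plane(pl, path)
  back <- read_plane(path)
  expect_equal(back$normal, pl$normal, tolerance = 1e-12)
  expect_equal(back$offset, pl$offset, tolerance = 1e-12)
})
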