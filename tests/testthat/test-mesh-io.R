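test_that("ASCII STL with one triangle parses to 3 vertices and 1 face", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid tri",
               "  facet normal 0 0 1",
               "    outer loop",
               "      vertex 0 0 0",
               "      vertex 1 0 0",
               "      vertex 0 1 0",
               "    endloop",
               "  endfacet",
               "endsolid tri"), path)
  m <- read_stl(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_true(all(m$tissue == "OTHER"))
})

test_that("STL round-trip preserves faces and vertex positions in both dialects", {
  arch <- small_arch()
  for (dialect in c("ascii", "binary")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(arch, path, dialect = dialect)
    back <- read_stl(path)
    expect_equal(nrow(back$faces), nrow(arch$faces))
    # welding may reorder vertices; compare as point sets
    d_fwd <- nearest_neighbors(arch$vertices, back$vertices)$distance
    d_rev <- nearest_neighbors(back$vertices, arch$vertices)$distance
    tol <- if (dialect == "ascii") 1e-6 else
      max(abs(arch$vertices)) * 2^-23 * sqrt(3) + 1e-9
    expect_lt(max(d_fwd, d_rev), tol)
  }
})

test_that("label sidecar round-trips bit-exactly", {
  arch <- small_arch()
  for (dialect in c("ascii", "binary")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(arch, path, dialect = dialect)
    expect_true(file.exists(paste0(sub("\\.stl$", "", path), ".labels.json")))
    back <- read_stl(path)
    # locate each read-back vertex in the original mesh by position and
    # check its labels transferred exactly
    nn <- nearest_neighbors(back$vertices, arch$vertices)
    expect_identical(back$tissue, arch$tissue[nn$index])
    expect_identical(back$tooth_id, arch$tooth_id[nn$index])
  }
})

test_that("malformed binary STL reports a parse error naming the byte", {
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(10L, con, size = 4, endian = "little")  # declares 10 triangles
  writeBin(as.raw(rep(0, 50)), con)                # supplies only one
  close(con)
  expect_error(read_stl(path), "parse error.*10 triangles")
})

test_that("writing an empty mesh errors and binary layout is exact", {
  empty <- labeled_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  path <- withr::local_tempfile(fileext = ".stl")
  expect_error(write_stl(empty, path), "empty")
  write_stl(one_triangle_mesh(), path, dialect = "binary")
  expect_equal(file.info(path)$size, 84 + 50)
  path2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(one_triangle_mesh(), path2, dialect = "ascii")
  expect_match(readLines(path2, n = 1), "^solid")
})

test_that("labeled_mesh enforces its invariants", {
  expect_error(labeled_mesh(rbind(c(0, 0, 0)), matrix(c(1L, 1L, 1L), 1)),
               "repeats")
  expect_error(labeled_mesh(rbind(c(0, 0, 0)), matrix(c(1L, 2L, 3L), 1)),
               "out of range")
  expect_error(labeled_mesh(rbind(c(NA, 0, 0)), matrix(integer(0), 0, 3)),
               "finite")
  # tooth_id forced to NA off tooth tissue
  m <- labeled_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    matrix(c(1L, 2L, 3L), 1),
                    tissue = c("GINGIVA", "TOOTH", "OTHER"),
                    tooth_id = c("11", "11", "11"))
  expect_identical(m$tooth_id, c(NA, "11", NA))
})

test_that("surface sampling is area-uniform, deterministic and in-face", {
  m <- two_triangle_mesh()
  cl <- sample_surface(m, 40000, seed = 9L)
  frac_large <- mean(cl$points[, 1] >= 5)  # second triangle lives at x >= 10
  p <- 0.75
  expect_lt(abs(frac_large - p), 3 * sqrt(p * (1 - p) / 40000))
  expect_identical(sample_surface(m, 100, seed = 4L)$points,
                   sample_surface(m, 100, seed = 4L)$points)
  expect_equal(n_points(sample_surface(m, 0, seed = 1L)), 0L)
  # brute-force membership: every sampled point lies inside some face
  small <- sample_surface(m, 200, seed = 2L)
  inside <- vapply(seq_len(200), function(i) {
    any(vapply(seq_len(nrow(m$faces)), function(fi) {
      point_in_face(small$points[i, ], m$vertices[m$faces[fi, 1], ],
                    m$vertices[m$faces[fi, 2], ], m$vertices[m$faces[fi, 3], ])
    }, logical(1)))
  }, logical(1))
  expect_true(all(inside))
})

test_that("sampled points inherit majority tissue labels", {
  m <- labeled_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    matrix(c(1L, 2L, 3L), 1),
                    tissue = c("TOOTH", "TOOTH", "GINGIVA"),
                    tooth_id = c("11", "11", NA))
  cl <- sample_surface(m, 50, seed = 1L)
  expect_true(all(cl$tissue == "TOOTH"))
  expect_true(all(cl$tooth_id == "11"))
  # three-way tie resolves to OTHER
  m2 <- labeled_mesh(m$vertices, m$faces,
                     tissue = c("TOOTH", "GINGIVA", "OTHER"))
  expect_true(all(sample_surface(m2, 20, seed = 1L)$tissue == "OTHER"))
})

test_that("template sampling requires identical connectivity and pairs points", {
  arch <- small_arch()
  pm <- degrade_to_pm(arch, degradation_params(), seed = 3L)
  a <- sample_surface(arch, 400, seed = 7L)
  b <- sample_surface(pm$mesh, 400, seed = 7L, template = arch)
  d <- sqrt(rowSums((transform_points(pm$truth, b$points) - a$points)^2))
  # corresponding points differ only by deformation + noise, never by mm-scale
  # sampling relocation
  expect_lt(max(d), 1.0)
  expect_error(sample_surface(two_triangle_mesh(), 10, seed = 1L,
                              template = one_triangle_mesh()),
               "connectivity")
})
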