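#' Labelled triangle mesh
#'
#' The unit of scan data: a triangle surface mesh in millimetres with a tissue
#' label (`"TOOTH"`, `"GINGIVA"` or `"OTHER"`) and, for tooth vertices, an FDI
#' two-digit tooth identifier per vertex. STL itself carries no attributes, so
#' labels travel in a JSON sidecar file (see [write_stl()]).
#'
#' @param vertices numeric `n x 3` matrix of coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param tissue character vector length `n` in `{"TOOTH","GINGIVA","OTHER"}`.
#' @param tooth_id character vector length `n` of FDI codes, `NA` off-tooth.
#' @param frame_id free-text coordinate-frame tag.
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, faces, tissue = NULL, tooth_id = NULL,
                         frame_id = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  n <- nrow(vertices)
  if (ncol(vertices) != 3L || (nrow(faces) > 0 && ncol(faces) != 3L))
    stopf("vertices and faces must have 3 columns")
  if (!all(is.finite(vertices))) stopf("mesh has non-finite coordinates")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > n)
      stopf("face index out of range (mesh has %d vertices)", n)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stopf("a face repeats a vertex index")
  }
  if (is.null(tissue)) tissue <- rep("OTHER", n)
  if (is.null(tooth_id)) tooth_id <- rep(NA_character_, n)
  tissue <- as.character(tissue)
  tooth_id <- as.character(tooth_id)
  if (length(tissue) != n || length(tooth_id) != n)
    stopf("label arrays must have exactly one entry per vertex")
  if (!all(tissue %in% c("TOOTH", "GINGIVA", "OTHER")))
    stopf("tissue labels must be TOOTH, GINGIVA or OTHER")
  tooth_id[tissue != "TOOTH"] <- NA_character_
  structure(list(vertices = vertices, faces = faces, tissue = tissue,
                 tooth_id = tooth_id, frame_id = as.character(frame_id)),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh: %d vertices, %d faces (%d TOOTH, %d GINGIVA, %d OTHER vertices)\n",
              nrow(x$vertices), nrow(x$faces), sum(x$tissue == "TOOTH"),
              sum(x$tissue == "GINGIVA"), sum(x$tissue == "OTHER")))
  ids <- unique(x$tooth_id[!is.na(x$tooth_id)])
  if (length(ids)) cat("  tooth ids:", paste(sort(ids), collapse = " "), "\n")
  invisible(x)
}

#' Point cloud
#'
#' Discrete 3D points (mm) optionally carrying tissue labels and tooth ids
#' inherited from the mesh they were sampled from. Registration and
#' segmentation operate on point clouds.
#'
#' @param points numeric `n x 3` matrix (mm).
#' @param tissue optional character vector length `n`.
#' @param tooth_id optional character vector length `n`.
#' @param frame_id free-text coordinate-frame tag.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, tissue = NULL, tooth_id = NULL, frame_id = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (nrow(points) > 0 && ncol(points) != 3L) stopf("points must be n x 3")
  if (!all(is.finite(points))) stopf("point cloud has non-finite coordinates")
  n <- nrow(points)
  if (!is.null(tissue) && length(tissue) != n)
    stopf("tissue labels must match point count")
  if (!is.null(tooth_id) && length(tooth_id) != n)
    stopf("tooth ids must match point count")
  structure(list(points = points,
                 tissue = if (is.null(tissue)) NULL else as.character(tissue),
                 tooth_id = if (is.null(tooth_id)) NULL else as.character(tooth_id),
                 frame_id = as.character(frame_id)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$tissue)) "" else " (labelled)"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by index, carrying labels along
#' @param cloud a [point_cloud()].
#' @param idx integer index vector.
#' @return The subsetted [point_cloud()].
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              tissue = if (is.null(cloud$tissue)) NULL else cloud$tissue[idx],
              tooth_id = if (is.null(cloud$tooth_id)) NULL else cloud$tooth_id[idx],
              frame_id = cloud$frame_id)
}

#' Apply a rigid transform to a point cloud
#' @param transform a [rigid_transform()].
#' @param cloud a [point_cloud()].
#' @param frame_id frame tag for the result.
#' @return The transformed [point_cloud()].
#' @export
transform_cloud <- function(transform, cloud, frame_id = cloud$frame_id) {
  out <- cloud
  out$points <- transform_points(transform, cloud$points)
  out$frame_id <- frame_id
  out
}

sidecar_path <- function(path) paste0(sub("\\.stl$", "", path, ignore.case = TRUE),
                                      ".labels.json")

#' Read an STL surface scan
#'
#' Reads binary or ASCII STL (auto-detected). STL stores a triangle soup, so
#' duplicate vertices within 1e-9 mm are merged to give faces shared vertex
#' indices. If a JSON label sidecar (`<stem>.labels.json`, as written by
#' [write_stl()]) sits next to the file it is loaded; otherwise every vertex
#' is labelled `OTHER`.
#'
#' @param path path to an `.stl` file.
#' @param frame_id coordinate-frame tag stored on the mesh.
#' @return A [labeled_mesh()].
#' @export
read_stl <- function(path, frame_id = basename(path)) {
  if (!file.exists(path)) stopf("STL file not found: %s", path)
  sz <- file.info(path)$size
  if (sz < 15) stopf("STL parse error in %s: file too short (%d bytes)", path, sz)
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  starts_solid <- identical(rawToChar(head84[1:5]), "solid")
  if (!is_binary && !starts_solid) {
    # binary file whose declared count does not match the payload
    if (sz >= 84) {
      ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
      stopf("STL parse error in %s: binary header declares %d triangles (expects %.0f bytes) but file has %.0f bytes",
            path, ntri, 84 + 50 * as.numeric(ntri), as.numeric(sz))
    }
    stopf("STL parse error in %s: neither valid binary nor ASCII", path)
  }
  tri <- if (is_binary) read_stl_binary(path, sz) else read_stl_ascii(path)
  if (nrow(tri) == 0) stopf("empty solid in %s", path)
  mesh <- weld_triangles(tri, frame_id = frame_id)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    lab <- jsonlite::fromJSON(sc)
    n <- nrow(mesh$vertices)
    if (length(lab$tissue) != n)
      stopf("label sidecar %s has %d entries for %d vertices", sc,
            length(lab$tissue), n)
    tid <- as.character(lab$tooth_id)
    tid[tid == "NA"] <- NA_character_
    mesh <- labeled_mesh(mesh$vertices, mesh$faces, lab$tissue, tid, frame_id)
  }
  mesh
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  payload <- readBin(con, "raw", n = 50 * ntri)
  if (length(payload) != 50 * ntri)
    stopf("STL parse error in %s at byte %d: truncated triangle payload", path,
          84 + length(payload))
  m <- matrix(payload, nrow = 50)
  coords <- matrix(readBin(as.raw(m[13:48, ]), "double", size = 4,
                           n = 9 * ntri, endian = "little"),
                   ncol = 9, byrow = TRUE)
  if (!all(is.finite(coords)))
    stopf("STL parse error in %s: non-finite vertex coordinate", path)
  coords
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) %% 3 != 0)
    stopf("STL parse error in %s at line %d: vertex count not a multiple of 3",
          path, if (length(vl)) vl[length(vl)] else 1L)
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stopf("STL parse error in %s at line %d: malformed vertex line", path, vl[bad[1]])
  vals <- suppressWarnings(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stopf("STL parse error in %s at line %d: non-numeric coordinate", path, vl[bad])
  }
  matrix(as.numeric(vals), ncol = 9, byrow = TRUE)
}

# Round doubles through float32 storage.
f32_round <- function(m) {
  out <- readBin(writeBin(as.numeric(m), raw(), size = 4, endian = "little"),
                 "double", size = 4, n = length(m), endian = "little")
  matrix(out, nrow(m), ncol(m))
}

# Vertex order the reader's welding pass will produce for this mesh: first
# occurrence of each unique position in the written triangle-soup traversal.
weld_order <- function(mesh, tol = 1e-9) {
  f <- mesh$faces
  soup <- rbind(mesh$vertices[f[, 1], , drop = FALSE],
                mesh$vertices[f[, 2], , drop = FALSE],
                mesh$vertices[f[, 3], , drop = FALSE])
  key <- paste(round(soup[, 1] / tol), round(soup[, 2] / tol),
               round(soup[, 3] / tol))
  ids <- c(f[, 1], f[, 2], f[, 3])
  ids[!duplicated(match(key, key))]
}

# Merge duplicate vertices of a triangle soup (rows = 9 coords per triangle).
weld_triangles <- function(tri, tol = 1e-9, frame_id = "") {
  v <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
             tri[, 7:9, drop = FALSE])
  nt <- nrow(tri)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  uid <- match(key, key)
  keep <- !duplicated(uid)
  remap <- cumsum(keep)[uid]
  verts <- v[keep, , drop = FALSE]
  faces <- cbind(remap[seq_len(nt)], remap[nt + seq_len(nt)],
                 remap[2 * nt + seq_len(nt)])
  ok <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  labeled_mesh(verts, faces[ok, , drop = FALSE], frame_id = frame_id)
}

#' Write an STL surface scan
#'
#' Writes binary (little-endian, 80-byte header + uint32 count + 50 bytes per
#' triangle) or ASCII STL. When any vertex label differs from `OTHER`, a JSON
#' sidecar `<stem>.labels.json` with fields `tissue` and `tooth_id` is written
#' alongside, since STL has no attribute channel.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output path.
#' @param dialect `"binary"` or `"ascii"`.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "labeled_mesh"))
  if (nrow(mesh$faces) == 0) stopf("refusing to write an empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrml <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrml^2))
  len[len == 0] <- 1
  nrml <- nrml / len
  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"), error = function(e)
      stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "odontomatch binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- t(cbind(nrml, a, b, cc))  # 12 floats per triangle
    fl <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    flm <- matrix(fl, nrow = 48)
    out <- rbind(flm, matrix(as.raw(0), nrow = 2, ncol = ncol(flm)))
    writeBin(as.raw(out), con)
  } else {
    con <- tryCatch(file(path, "wt"), error = function(e)
      stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
    on.exit(close(con))
    name <- "odontomatch"
    writeLines(paste("solid", name), con)
    fmt <- paste0(
      "  facet normal %.17g %.17g %.17g\n    outer loop\n",
      "      vertex %.17g %.17g %.17g\n      vertex %.17g %.17g %.17g\n",
      "      vertex %.17g %.17g %.17g\n    endloop\n  endfacet")
    body <- sprintf(fmt, nrml[, 1], nrml[, 2], nrml[, 3],
                    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                    cc[, 1], cc[, 2], cc[, 3])
    writeLines(body, con)
    writeLines(paste("endsolid", name), con)
  }
  if (any(mesh$tissue != "OTHER")) {
    # labels are keyed by the vertex order read_stl reconstructs after
    # welding; for binary output the reader sees float32 coordinates, so the
    # welding pattern is computed on the rounded values
    key_mesh <- mesh
    if (dialect == "binary") key_mesh$vertices <- f32_round(mesh$vertices)
    ord <- weld_order(key_mesh)
    jsonlite::write_json(list(tissue = mesh$tissue[ord],
                              tooth_id = mesh$tooth_id[ord]),
                         sidecar_path(path), null = "null", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Sample a point cloud from a mesh surface
#'
#' Draws points area-uniformly over the faces of a mesh. Faces are chosen by
#' inversion sampling on cumulative face areas (so nearly identical meshes
#' sampled with the same seed yield nearly corresponding points), positions by
#' uniform barycentric coordinates. Each point inherits the tissue label held
#' by the majority of its face's vertices; a three-way tie is resolved to
#' `OTHER` (never inventing tooth surface).
#'
#' When `template` is supplied (a mesh with identical face connectivity, e.g.
#' the AM scan a PM scan was derived from), face selection probabilities are
#' computed from the template's areas instead, so two meshes sampled with the
#' same seed and template yield parametrically corresponding point pairs.
#' This makes the RMS between the clouds reflect true surface deviation
#' rather than sampling-density noise, emulating the cloud-to-mesh distances
#' that dense real scans provide.
#'
#' @param mesh a [labeled_mesh()] with at least one positive-area face.
#' @param n number of points to draw.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param template optional [labeled_mesh()] with the identical face matrix,
#'   used as the area reference for face selection.
#' @return A [point_cloud()] with `n` points.
#' @export
sample_surface <- function(mesh, n, seed = 1L, template = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  if (n < 0) stopf("n must be non-negative")
  f <- mesh$faces
  v <- mesh$vertices
  if (!is.null(template)) {
    stopifnot(inherits(template, "labeled_mesh"))
    if (!identical(template$faces, f))
      stopf("template mesh must share the exact face connectivity")
    v_area <- template$vertices
  } else {
    v_area <- v
  }
  aa <- v_area[f[, 1], , drop = FALSE]
  ab <- v_area[f[, 2], , drop = FALSE]
  ac <- v_area[f[, 3], , drop = FALSE]
  e1 <- ab - aa
  e2 <- ac - aa
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (nrow(f) == 0 || all(area <= 0)) stopf("mesh has no positive-area faces")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  if (n == 0) {
    return(point_cloud(matrix(0, 0, 3), tissue = character(0),
                       tooth_id = character(0), frame_id = mesh$frame_id))
  }
  cum <- cumsum(area) / sum(area)
  with_seed(seed, {
    u <- runif(n)
    fi <- findInterval(u, cum, rightmost.closed = TRUE) + 1L
    fi[fi > length(area)] <- length(area)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    w1 <- 1 - r1
    w2 <- r1 * (1 - r2)
    w3 <- r1 * r2
    pts <- w1 * a[fi, , drop = FALSE] + w2 * b[fi, , drop = FALSE] +
      w3 * cc[fi, , drop = FALSE]
    lab3 <- cbind(mesh$tissue[f[fi, 1]], mesh$tissue[f[fi, 2]],
                  mesh$tissue[f[fi, 3]])
    tis <- ifelse(lab3[, 1] == lab3[, 2] | lab3[, 1] == lab3[, 3], lab3[, 1],
                  ifelse(lab3[, 2] == lab3[, 3], lab3[, 2], "OTHER"))
    id3 <- cbind(mesh$tooth_id[f[fi, 1]], mesh$tooth_id[f[fi, 2]],
                 mesh$tooth_id[f[fi, 3]])
    tid <- ifelse(tis == "TOOTH",
                  ifelse(!is.na(id3[, 1]) &
                           (identical_na(id3[, 1], id3[, 2]) |
                              identical_na(id3[, 1], id3[, 3])), id3[, 1],
                         ifelse(!is.na(id3[, 2]) & identical_na(id3[, 2], id3[, 3]),
                                id3[, 2], NA_character_)),
                  NA_character_)
    point_cloud(pts, tissue = tis, tooth_id = tid, frame_id = mesh$frame_id)
  })
}

identical_na <- function(x, y) !is.na(x) & !is.na(y) & x == y
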