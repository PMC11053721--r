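# STL and region-sidecar I/O.  STL carries no topology or labels: faces are
# written as independent triangles and vertices are re-welded on read within
# a 1e-6 mm tolerance; region labels travel in a JSON sidecar keyed by region
# name -> 1-based face-index list (face order is preserved by STL round trips).

#' Write a mesh as STL
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file.
#' @param format `"binary"` (little-endian, 50-byte triangle records) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  nf <- nrow(mesh$faces)
  if (nf == 0) stop("refusing to write an empty mesh")
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  nrm <- face_normals(mesh)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "truedent structurized dental model"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats per triangle, written in one call; attribute counts after
    dat <- t(cbind(nrm, v1, v2, v3))
    for (i in seq_len(nf)) {
      writeBin(dat[, i], con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid truedent", con)
    body <- sprintf(
      "facet normal %.9e %.9e %.9e\nouter loop\nvertex %.9e %.9e %.9e\nvertex %.9e %.9e %.9e\nvertex %.9e %.9e %.9e\nendloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(body, con)
    writeLines("endsolid truedent", con)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects binary versus ASCII encoding.  Vertices are deduplicated
#' within a 1e-6 mm tolerance; triangle order is preserved.  The returned
#' mesh has no regions (attach them with [read_regions()] / [read_model()]).
#'
#' @param path STL file (binary or ASCII).
#' @return a `labeled_mesh` with empty `regions`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sz <- file.info(path)$size
  if (sz < 15) stop(sprintf("malformed STL '%s': only %d bytes", path, sz))
  head <- readBin(path, "raw", n = min(sz, 84))
  is_binary <- FALSE
  if (sz >= 84) {
    nf <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(nf) && nf >= 0 && sz == 84 + 50 * as.numeric(nf)) is_binary <- TRUE
  }
  starts_solid <- identical(rawToChar(head[1:5]), "solid")
  if (!is_binary && !starts_solid)
    stop(sprintf("malformed STL '%s': not ASCII ('solid' missing at byte 0) and size %d inconsistent with a binary triangle count", path, sz))
  tri <- if (is_binary) read_stl_binary(path, sz) else read_stl_ascii(path)
  weld_triangles(tri)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", size = 4, endian = "little")
  rec <- readBin(con, "raw", n = 50 * nf)
  if (length(rec) < 50 * nf)
    stop(sprintf("malformed STL '%s': truncated at byte %d (expected %d triangles)",
                 path, 84 + length(rec), nf))
  idx <- rep(seq(0, by = 50, length.out = nf), each = 36) +
    rep(12 + seq_len(36), times = nf)
  vals <- readBin(rec[idx], "numeric", n = 9 * nf, size = 4, endian = "little")
  matrix(vals, ncol = 9, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3)",
                 path, length(vl)))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(nums)) stop(sprintf("malformed ASCII STL '%s': unparsable vertex line", path))
  matrix(as.vector(t(nums)), ncol = 9, byrow = TRUE)
}

# Weld an n x 9 soup (v1 v2 v3 per row) into an indexed mesh; tolerance 1e-6.
weld_triangles <- function(tri) {
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(round(pts[, 1] * 1e6), round(pts[, 2] * 1e6), round(pts[, 3] * 1e6))
  first <- !duplicated(key)
  id <- match(key, key[first])
  labeled_mesh(pts[first, , drop = FALSE],
               matrix(id, ncol = 3), list())
}

#' Read/write a region-label sidecar
#'
#' The sidecar is JSON mapping region name to a list of 1-based face indices
#' of the accompanying STL; it round-trips the `regions` field of a
#' `labeled_mesh` losslessly.
#'
#' @param regions named list of integer face-index vectors.
#' @param path sidecar file path.
#' @return `write_regions`: `path` invisibly; `read_regions`: the named list.
#' @export
write_regions <- function(regions, path) {
  jsonlite::write_json(lapply(regions, as.integer), path)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop(sprintf("region sidecar not found: %s", path))
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.integer)
}

#' Export a labeled mesh as STL plus region sidecar
#'
#' @param mesh a `labeled_mesh`.
#' @param path output STL path; the sidecar is written next to it as
#'   `<path>.regions.json` unless `sidecar` is given.
#' @param sidecar optional explicit sidecar path.
#' @param format STL encoding, see [write_stl()].
#' @return named character vector with the two paths, invisibly.
#' @export
export_model <- function(mesh, path, sidecar = paste0(path, ".regions.json"),
                         format = "binary") {
  if (!inherits(mesh, "labeled_mesh") || nrow(mesh$faces) == 0)
    stop("refusing to export an empty mesh")
  write_stl(mesh, path, format)
  write_regions(mesh$regions, sidecar)
  invisible(c(stl = path, regions = sidecar))
}

#' @rdname export_model
#' @export
read_model <- function(path, sidecar = paste0(path, ".regions.json")) {
  mesh <- read_stl(path)
  mesh$regions <- lapply(read_regions(sidecar), as.integer)
  labeled_mesh(mesh$vertices, mesh$faces, mesh$regions)
}

#' Sample points on labeled regions
#'
#' Area-weighted uniform sampling of each named region's surface: the number
#' of points per region is `round(area * density)`, triangles are drawn with
#' probability proportional to their area and points placed by the uniform
#' barycentric construction.  Deterministic given `seed`.
#'
#' @param mesh a `labeled_mesh`.
#' @param region_names regions to sample.
#' @param density points per mm^2 (default 25, about a 0.2 mm grid).
#' @param seed integer RNG seed.
#' @return list of `region_point_set`s: `region`, `points` (n x 3), `face`
#'   (source face index per point), `density`.
#' @export
sample_regions <- function(mesh, region_names, density = 25, seed = 1) {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  missing <- setdiff(region_names, names(mesh$regions))
  if (length(missing))
    stop(sprintf("unknown region(s): %s", paste(missing, collapse = ", ")))
  with_seed(seed, lapply(region_names, function(rn) {
    idx <- mesh$regions[[rn]]
    areas <- triangle_areas(mesh, idx)
    n <- max(1L, round(sum(areas) * density))
    pick <- sample.int(length(idx), n, replace = TRUE, prob = areas)
    f <- mesh$faces[idx[pick], , drop = FALSE]
    a <- mesh$vertices[f[, 1], , drop = FALSE]
    b <- mesh$vertices[f[, 2], , drop = FALSE]
    c_ <- mesh$vertices[f[, 3], , drop = FALSE]
    r1 <- runif(n); r2 <- runif(n)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]; r2[flip] <- 1 - r2[flip]
    structure(list(region = rn,
                   points = a + r1 * (b - a) + r2 * (c_ - a),
                   face = idx[pick], density = density),
              class = "region_point_set")
  }))
}

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Transfer region labels from a reference mesh to a test mesh
#'
#' Replaces manual surface selection: after registration, each test face
#' inherits the region of the nearest labeled reference face (nearest by
#' point-to-triangle distance from the test face centroid), provided that
#' distance is below `cutoff`; faces further away are collected in an
#' `"unassigned"` region.  When the nearest reference face is oppositely
#' oriented to the test face (as happens where a crown's gingival-contact
#' face is coplanar with the base's upper surface), the nearest face with a
#' compatible normal is used instead, so back-to-back coplanar surfaces
#' keep their own labels.  Idempotent.
#'
#' @param reference labeled reference mesh.
#' @param test_mesh test mesh (regions ignored).
#' @param transform `rigid_transform` mapping test into the reference frame.
#' @param cutoff assignment distance cutoff, mm.
#' @return `test_mesh` with inherited regions.
#' @export
transfer_labels <- function(reference, test_mesh, transform = identity_transform(),
                            cutoff = 0.5) {
  if (!length(reference$regions)) stop("reference mesh has no regions")
  ref_faces <- unlist(reference$regions, use.names = FALSE)
  labels <- rep(names(reference$regions), lengths(reference$regions))
  test_r <- transform_mesh(test_mesh, transform)
  cent <- face_centroids(test_r)
  tn <- face_normals(test_r)
  rn <- face_normals(reference, ref_faces)
  hit <- cpp_closest_on_mesh(cent, reference$vertices,
                             reference$faces[ref_faces, , drop = FALSE])
  best_face <- hit$face
  best_dist <- hit$distance
  # orientation-incompatible winners (e.g. coplanar back-to-back surfaces):
  # retry on the subset of reference faces oriented like the test face, and
  # keep the retry only when it still lands within the cutoff
  bad <- which(rowSums(tn * rn[best_face, , drop = FALSE]) < 0.5 &
                 best_dist <= cutoff)
  for (i in bad) {
    ok <- which(as.numeric(rn %*% tn[i, ]) >= 0.5)
    if (!length(ok)) next
    h <- cpp_closest_on_mesh(cent[i, , drop = FALSE], reference$vertices,
                             reference$faces[ref_faces[ok], , drop = FALSE])
    if (h$distance <= cutoff) {
      best_face[i] <- ok[h$face]
      best_dist[i] <- h$distance
    }
  }
  lab <- ifelse(best_dist <= cutoff, labels[best_face], "unassigned")
  test_mesh$regions <- lapply(split(seq_len(nrow(cent)), lab), as.integer)
  test_mesh
}
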