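# Construction of the structurized dental model mesh: 14 cuboid SDCs sitting
# on a horseshoe base strip, every measurement surface a labeled face region.

labeled_mesh <- function(vertices, faces, regions = list()) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || (nrow(faces) > 0 && ncol(faces) != 3))
    stop("vertices must be n x 3 and faces m x 3")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  regions <- lapply(regions, as.integer)
  if (length(regions)) {
    all_idx <- unlist(regions, use.names = FALSE)
    if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > nrow(faces)))
      stop("region face indices out of range")
    if (anyDuplicated(all_idx))
      stop("region face sets must be pairwise disjoint")
  }
  structure(list(vertices = vertices, faces = faces, regions = regions,
                 frame = c(occlusal = "X-Y", occlusogingival = "Z")),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled mesh: %d vertices, %d faces, %d regions (mm; occlusal plane X-Y)\n",
              nrow(x$vertices), nrow(x$faces), length(x$regions)))
  invisible(x)
}

# Two CCW triangles for the quad a-b-c-d (as vertex indices).
quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))

# Closed cuboid given by an in-plane rectangle frame and a z-range.
# Returns vertices, faces and a region -> local face rows map.
cuboid_solid <- function(center, u, v, md, bl, z0, z1) {
  corner <- function(su, sv, z)
    c(center + su * md / 2 * u + sv * bl / 2 * v, z)
  verts <- rbind(
    corner(-1, -1, z0), corner(1, -1, z0), corner(1, 1, z0), corner(-1, 1, z0),
    corner(-1, -1, z1), corner(1, -1, z1), corner(1, 1, z1), corner(-1, 1, z1))
  faces <- rbind(
    quad(1, 4, 3, 2),  # bottom, outward -z  (gingival contact)
    quad(5, 6, 7, 8),  # top, outward +z     (occlusal)
    quad(1, 2, 6, 5),  # -v side             (lingual)
    quad(2, 3, 7, 6),  # +u side             (distal)
    quad(3, 4, 8, 7),  # +v side             (buccal)
    quad(4, 1, 5, 8))  # -u side             (mesial)
  # the windings above assume a right-handed (u, v, z) frame; mirrored
  # (left-side) placements hand over a left-handed one -> flip windings
  if (u[1] * v[2] - u[2] * v[1] < 0) faces <- faces[, c(1, 3, 2)]
  regions <- list(gingival = 1:2, occlusal = 3:4, lingual = 5:6,
                  distal = 7:8, buccal = 9:10, mesial = 11:12)
  list(vertices = verts, faces = faces, regions = regions)
}

# Horseshoe base solid: the arch strip of half-width w around the centerline,
# extruded from z = 0 to z = thickness.
base_solid <- function(curve, s_end, w, thickness, step = 1.5) {
  n <- 2L * ceiling(s_end / step) + 1L       # odd, symmetric sample of s
  sgrid <- seq(-s_end, s_end, length.out = n)
  p <- arch_point(curve, sgrid)
  inner <- cbind(p$x - w * p$nx, p$y - w * p$ny)
  outer <- cbind(p$x + w * p$nx, p$y + w * p$ny)
  # vertex layout: for i in 1..n -> 4 rows: inner/outer at top, inner/outer at bottom
  it <- function(i) 4L * (i - 1L) + 1L
  ot <- function(i) 4L * (i - 1L) + 2L
  ib <- function(i) 4L * (i - 1L) + 3L
  ob <- function(i) 4L * (i - 1L) + 4L
  verts <- matrix(0, 4L * n, 3L)
  verts[it(1:n), ] <- cbind(inner, thickness)
  verts[ot(1:n), ] <- cbind(outer, thickness)
  verts[ib(1:n), ] <- cbind(inner, 0)
  verts[ob(1:n), ] <- cbind(outer, 0)
  top <- NULL; bottom <- NULL; owall <- NULL; iwall <- NULL
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    top    <- rbind(top,    quad(it(i), it(j), ot(j), ot(i)))
    bottom <- rbind(bottom, quad(ib(i), ob(i), ob(j), ib(j)))
    owall  <- rbind(owall,  quad(ob(j), ob(i), ot(i), ot(j)))
    iwall  <- rbind(iwall,  quad(ib(i), ib(j), it(j), it(i)))
  }
  cap_r <- quad(ib(n), ob(n), ot(n), it(n))   # outward +tangent at s = +s_end
  cap_l <- quad(ob(1), ib(1), it(1), ot(1))   # outward -tangent at s = -s_end
  faces <- rbind(top, bottom, owall, iwall, cap_r, cap_l)
  nt <- nrow(top)
  regions <- list(
    upper = seq_len(nt),
    lower = nt + seq_len(nrow(bottom)),
    wall = 2L * nt + seq_len(nrow(owall) + nrow(iwall) + 4L))
  list(vertices = verts, faces = faces, regions = regions)
}

#' Build the structurized dental model mesh
#'
#' Generates the labeled triangle mesh of one jaw's structurized model: each
#' SDC is a closed cuboid of its MD x BL x CH dimensions standing on the
#' horseshoe base's upper surface (occlusal face at
#' `z = base_thickness + CH`), with its mesiodistal axis along the arch
#' tangent.  Every cuboid contributes six labeled face regions
#' (`"<code>:occlusal"`, `:buccal`, `:lingual`, `:mesial`, `:distal`,
#' `:gingival`); the base contributes `"base:upper"`, `"base:lower"` and
#' `"base:wall"`.  The gingival-contact face is bookkeeping only and is
#' excluded from all metrics.  Each connected component of the returned mesh
#' is a closed, consistently outward-oriented solid.
#'
#' @param spec a `model_spec` (see [default_spec()]).
#' @return A `labeled_mesh` with fields `vertices` (n x 3, mm), `faces`
#'   (m x 3, 1-based), `regions` (named list of face-index vectors), `frame`.
#' @examples
#' mesh <- build_model(default_spec("maxillary"))
#' range(mesh$vertices[, 3])  # 0 to base_thickness + max crown height
#' @export
build_model <- function(spec) {
  validate_spec(spec)
  pl <- sdc_placements(spec)
  validate_placements(pl)
  curve <- arch_curve(spec$arch$curvature)
  thick <- spec$arch$base_thickness

  verts <- NULL; faces <- NULL; regions <- list()
  add_solid <- function(solid, prefix) {
    off_v <- if (is.null(verts)) 0L else nrow(verts)
    off_f <- if (is.null(faces)) 0L else nrow(faces)
    verts <<- rbind(verts, solid$vertices)
    faces <<- rbind(faces, solid$faces + off_v)
    for (nm in names(solid$regions))
      regions[[paste0(prefix, ":", nm)]] <<- solid$regions[[nm]] + off_f
  }

  for (i in seq_len(nrow(pl))) {
    solid <- cuboid_solid(c(pl$cx[i], pl$cy[i]),
                          c(pl$ux[i], pl$uy[i]), c(pl$vx[i], pl$vy[i]),
                          pl$md[i], pl$bl[i], thick, thick + pl$ch[i])
    add_solid(solid, pl$code[i])
  }

  # base half-width: widest footprint corner off the centerline plus margin
  corner_pts <- do.call(rbind, lapply(seq_len(nrow(pl)), function(i) {
    u <- c(pl$ux[i], pl$uy[i]); v <- c(pl$vx[i], pl$vy[i]); c0 <- c(pl$cx[i], pl$cy[i])
    rbind(c0 + pl$md[i] / 2 * u + pl$bl[i] / 2 * v,
          c0 + pl$md[i] / 2 * u - pl$bl[i] / 2 * v,
          c0 - pl$md[i] / 2 * u - pl$bl[i] / 2 * v,
          c0 - pl$md[i] / 2 * u + pl$bl[i] / 2 * v)
  }))
  dense_s <- seq(0, curve$s_max, by = 0.05)
  dp <- arch_point(curve, dense_s)
  dxy <- cbind(dp$x, dp$y)
  nearest <- vapply(seq_len(nrow(corner_pts)), function(k) {
    d2 <- (dxy[, 1] - abs(corner_pts[k, 1]))^2 + (dxy[, 2] - corner_pts[k, 2])^2
    i <- which.min(d2)
    c(sqrt(d2[i]), dense_s[i])
  }, numeric(2))
  w <- max(nearest[1, ]) + spec$arch$base_margin
  s_end <- max(abs(pl$s)) + max(pl$md) / 2 + spec$arch$end_margin
  s_end <- max(s_end, max(nearest[2, ]) + spec$arch$end_margin)
  add_solid(base_solid(curve, s_end, w, thick), "base")

  labeled_mesh(verts, faces, regions)
}

# --- mesh helpers used across the package ---------------------------------

face_normals <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

face_centroids <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  (mesh$vertices[f[, 1], , drop = FALSE] +
   mesh$vertices[f[, 2], , drop = FALSE] +
   mesh$vertices[f[, 3], , drop = FALSE]) / 3
}

triangle_areas <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

region_vertices <- function(mesh, region) {
  idx <- mesh$regions[[region]]
  if (is.null(idx)) stop(sprintf("unknown region '%s'", region))
  mesh$vertices[unique(as.vector(mesh$faces[idx, ])), , drop = FALSE]
}

# Area-weighted mean normal of a region (the design normal for flat regions).
region_normal <- function(mesh, region) {
  idx <- mesh$regions[[region]]
  if (is.null(idx)) stop(sprintf("unknown region '%s'", region))
  n <- face_normals(mesh, idx) * triangle_areas(mesh, idx)
  n <- colSums(n)
  n / sqrt(sum(n^2))
}

#' Check that a mesh is watertight
#'
#' A mesh is watertight here when every edge is shared by exactly two faces
#' with opposite orientation, i.e. every connected component is a closed,
#' consistently oriented solid.
#'
#' @param mesh a `labeled_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  half <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(half[, 1], half[, 2])
  rkey <- paste(half[, 2], half[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}
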