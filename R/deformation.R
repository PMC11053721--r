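# Synthetic print-like deformations: known, parameterized distortions
# applied to a reference mesh so the whole evaluation pipeline can be
# validated in closed loop against ground truth.

#' Deformation parameters
#'
#' Describes one synthetic printed-model deformation: anisotropic linear
#' scale error (in-plane vs vertical), bowl-like base warpage, surface noise
#' along vertex normals (scanner/surface error), and a small random rigid
#' displacement.  All geometric steps are applied about the undeformed
#' mesh's vertex centroid.
#'
#' @param xy_scale in-plane (X-Y) scale factor; 0.99 is 1 % transversal
#'   shrinkage.
#' @param z_scale occlusogingival (Z) scale factor.
#' @param warp_k base-bowing coefficient, mm^-1: vertices rise by
#'   `warp_k * r^2` with `r` the in-plane distance from the centroid axis.
#' @param noise_sd standard deviation (mm) of Gaussian displacement along
#'   vertex normals.
#' @param jitter_rot,jitter_trans magnitudes of the random rigid jitter
#'   (degrees about a random axis; mm along a random direction).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `deformation_params` list.
#' @export
deformation_params <- function(xy_scale = 1, z_scale = 1, warp_k = 0,
                               noise_sd = 0, jitter_rot = 0, jitter_trans = 0,
                               seed = 1) {
  if (xy_scale <= 0.5 || xy_scale >= 1.5 || z_scale <= 0.5 || z_scale >= 1.5)
    stop("scale factors must lie in (0.5, 1.5)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(xy_scale = xy_scale, z_scale = z_scale, warp_k = warp_k,
                 noise_sd = noise_sd, jitter_rot = jitter_rot,
                 jitter_trans = jitter_trans, seed = as.integer(seed)),
            class = "deformation_params")
}

# Area-weighted vertex normals.
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * triangle_areas(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (j in 1:3) {
      acc <- rowsum(fn[, j], mesh$faces[, k], reorder = FALSE)
      vn[as.integer(rownames(acc)), j] <- vn[as.integer(rownames(acc)), j] + acc
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

#' Apply a synthetic deformation to a mesh
#'
#' Vertex displacements are applied in a fixed, documented order: anisotropic
#' scale about the centroid (xy_scale on X and Y, z_scale on Z), then warp
#' (`z += warp_k * r^2` about the centroid axis), then seeded Gaussian noise
#' along vertex normals, then the rigid jitter.  Region labels are
#' preserved.
#'
#' @param mesh a `labeled_mesh`.
#' @param params a [deformation_params()].
#' @return the deformed `labeled_mesh`.
#' @export
apply_deformation <- function(mesh, params) {
  stopifnot(inherits(params, "deformation_params"))
  v <- mesh$vertices
  ctr <- colMeans(v)
  v <- sweep(v, 2, ctr)
  v[, 1] <- v[, 1] * params$xy_scale
  v[, 2] <- v[, 2] * params$xy_scale
  v[, 3] <- v[, 3] * params$z_scale
  if (params$warp_k != 0)
    v[, 3] <- v[, 3] + params$warp_k * (v[, 1]^2 + v[, 2]^2)
  v <- sweep(v, 2, -ctr)
  if (params$noise_sd > 0 || params$jitter_rot > 0 || params$jitter_trans > 0) {
    with_seed(params$seed, {
      if (params$noise_sd > 0) {
        vn <- vertex_normals(mesh)
        v <- v + rnorm(nrow(v), sd = params$noise_sd) * vn
      }
      if (params$jitter_rot > 0 || params$jitter_trans > 0) {
        axis <- rnorm(3); dir <- rnorm(3)
        R <- rotation_about_axis(axis, params$jitter_rot)
        tr <- params$jitter_trans * dir / sqrt(sum(dir^2))
        v <- sweep(sweep(v, 2, ctr) %*% t(R), 2, -(ctr + tr))
      }
    })
  }
  mesh$vertices <- v
  mesh
}

#' Default fixture grid
#'
#' Deformation cases spanning the error ranges reported for photopolymer
#' printers (tens of micrometres to about one percent): pure in-plane
#' shrinkage, pure vertical shrinkage, pure base warpage, a combined case,
#' and a noisy combined case.
#'
#' @return data frame of deformation parameters, one fixture per row.
#' @export
default_fixture_grid <- function() {
  data.frame(
    name = c("xy_shrink", "z_shrink", "warp", "combined", "noisy"),
    xy_scale = c(0.99, 1, 1, 0.99, 0.99),
    z_scale = c(1, 0.995, 1, 0.995, 0.995),
    warp_k = c(0, 0, 2e-5, 2e-5, 2e-5),
    noise_sd = c(0, 0, 0, 0, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Generate a deformed-fixture suite
#'
#' Applies every grid row to both reference meshes and writes each fixture
#' as STL plus region sidecar, together with a manifest recording the true
#' deformation parameters per fixture.  Byte-identical given the same seed.
#'
#' @param reference_max,reference_mand the two reference `labeled_mesh`es.
#' @param grid data frame of deformation parameters (see
#'   [default_fixture_grid()]); a `name` column is used for file names.
#' @param dir output directory (created if needed).
#' @param seed base seed; fixture i uses `seed + i`.
#' @return the manifest data frame (also written as `manifest.csv`),
#'   invisibly.
#' @export
generate_fixture_suite <- function(reference_max, reference_mand,
                                   grid = default_fixture_grid(), dir,
                                   seed = 1) {
  if (nrow(grid) == 0) stop("empty fixture grid")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- list(maxillary = reference_max, mandibular = reference_mand)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (jaw in names(refs)) {
      nm <- if ("name" %in% names(grid)) grid$name[i] else sprintf("case%02d", i)
      params <- deformation_params(
        xy_scale = grid$xy_scale[i], z_scale = grid$z_scale[i],
        warp_k = grid$warp_k[i], noise_sd = grid$noise_sd[i],
        jitter_rot = if ("jitter_rot" %in% names(grid)) grid$jitter_rot[i] else 0,
        jitter_trans = if ("jitter_trans" %in% names(grid)) grid$jitter_trans[i] else 0,
        seed = seed + i)
      stl <- file.path(dir, sprintf("%s_%s.stl", nm, jaw))
      export_model(apply_deformation(refs[[jaw]], params), stl)
      rows[[length(rows) + 1L]] <- data.frame(
        fixture = nm, jaw = jaw, stl = basename(stl),
        regions = paste0(basename(stl), ".regions.json"),
        xy_scale = params$xy_scale, z_scale = params$z_scale,
        warp_k = params$warp_k, noise_sd = params$noise_sd,
        jitter_rot = params$jitter_rot, jitter_trans = params$jitter_trans,
        seed = params$seed, aligned = params$jitter_rot == 0 &&
          params$jitter_trans == 0,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
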