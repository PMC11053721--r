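# Region-restricted best-fit rigid registration: point-to-plane ICP of
# points sampled on the test mesh against the reference surface, restricted
# to the registration regions (base upper surface plus the occlusal, buccal
# and lingual faces of every SDC; the narrow interproximal mesial/distal
# faces are excluded because scanners resolve them poorly).

#' Default registration regions of a labeled mesh
#'
#' @param mesh a `labeled_mesh` (typically the reference).
#' @return character vector: `"base:upper"` and every `*:occlusal`,
#'   `*:buccal`, `*:lingual` region present.
#' @export
registration_regions <- function(mesh) {
  nm <- names(mesh$regions)
  c(intersect("base:upper", nm),
    grep(":(occlusal|buccal|lingual)$", nm, value = TRUE))
}

#' Coarse pre-alignment of a test mesh to a reference
#'
#' Centroid translation plus principal-axes rotation.  The principal axes of
#' the vertex cloud are sign-ambiguous, so the four proper-rotation sign
#' combinations are scored by the mean distance of a vertex subsample to the
#' reference surface and the best is returned.  Falls back to pure centroid
#' translation (with a warning) when the inertia is degenerate.
#'
#' @param test,reference `labeled_mesh` objects.
#' @return a `rigid_transform` suitable as an ICP seed.
#' @export
initialize_alignment <- function(test, reference) {
  ct <- colMeans(test$vertices)
  cr <- colMeans(reference$vertices)
  if (nrow(test$vertices) < 4) {
    warning("degenerate test mesh: falling back to centroid translation")
    return(rigid_transform(diag(3), cr - ct))
  }
  et <- eigen(stats::cov(test$vertices), symmetric = TRUE)
  er <- eigen(stats::cov(reference$vertices), symmetric = TRUE)
  rel <- abs(diff(et$values)) / max(et$values)
  if (any(!is.finite(rel)) || min(rel) < 1e-6) {
    warning("degenerate principal axes: falling back to centroid translation")
    return(rigid_transform(diag(3), cr - ct))
  }
  sub <- test$vertices[unique(round(seq(1, nrow(test$vertices), length.out = 250))), ,
                       drop = FALSE]
  best <- NULL; best_score <- Inf
  for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    S <- diag(c(1, s2, s3))
    R <- er$vectors %*% S %*% t(et$vectors)
    if (det(R) < 0) R <- er$vectors %*% diag(c(-1, s2, s3)) %*% t(et$vectors)
    tf <- rigid_transform(R, cr - as.numeric(R %*% ct))
    d <- cpp_closest_on_mesh(apply_transform(sub, tf),
                             reference$vertices, reference$faces)$distance
    if (mean(d) < best_score) { best_score <- mean(d); best <- tf }
  }
  best
}

#' Best-fit rigid registration (point-to-plane ICP)
#'
#' Iteratively minimizes the mean squared point-to-surface distance from
#' points sampled on the test mesh to the reference surface, restricted to
#' the named regions, over rigid transforms.  Convergence is declared when
#' the RMS residual changes by less than `tol` between iterations;
#' non-convergence within `max_iter` produces a warning and a transform
#' flagged `converged = FALSE`.
#'
#' @param test test `labeled_mesh` (a printed-model scan or fixture).
#' @param reference labeled reference mesh.
#' @param region_names regions (on the reference; used on the test too when
#'   present there) to register on; defaults to [registration_regions()].
#' @param options list: `density` (points per mm^2 sampled on the test,
#'   default 5), `max_iter` (200), `tol` (1e-7 mm), `seed` (1), `init`
#'   (a `rigid_transform`, default [initialize_alignment()]).
#' @return a `rigid_transform` mapping test into the reference frame, with
#'   attributes `residual` (final RMS, mm), `iterations`, `converged`.
#' @export
best_fit_register <- function(test, reference,
                              region_names = registration_regions(reference),
                              options = list()) {
  if (nrow(test$faces) == 0 || nrow(reference$faces) == 0)
    stop("both meshes must be non-empty")
  if (length(region_names) == 0) stop("empty region selection")
  missing <- setdiff(region_names, names(reference$regions))
  if (length(missing))
    stop(sprintf("regions not on reference: %s", paste(missing, collapse = ", ")))
  o <- utils::modifyList(list(density = 5, max_iter = 200, tol = 1e-7,
                              seed = 1, init = NULL), options)

  ref_faces <- unlist(reference$regions[region_names], use.names = FALSE)
  RV <- reference$vertices
  RF <- reference$faces[ref_faces, , drop = FALSE]
  RN <- face_normals(reference, ref_faces)

  sample_from <- if (all(region_names %in% names(test$regions))) region_names
                 else names(test$regions)
  P0 <- if (length(sample_from)) {
    do.call(rbind, lapply(sample_regions(test, sample_from, o$density, o$seed),
                          `[[`, "points"))
  } else {
    do.call(rbind, lapply(sample_regions(
      labeled_mesh(test$vertices, test$faces,
                   list(all = seq_len(nrow(test$faces)))),
      "all", o$density, o$seed), `[[`, "points"))
  }

  tf <- if (is.null(o$init)) initialize_alignment(test, reference) else o$init
  rms_prev <- Inf; converged <- FALSE; it <- 0L; rms <- NA_real_
  while (it < o$max_iter) {
    it <- it + 1L
    P <- apply_transform(P0, tf)
    hit <- cpp_closest_on_mesh(P, RV, RF)
    N <- RN[hit$face, , drop = FALSE]
    d <- rowSums((P - hit$closest) * N)   # signed point-to-plane residual
    rms <- sqrt(mean(d^2))
    if (abs(rms_prev - rms) < o$tol) { converged <- TRUE; break }
    rms_prev <- rms
    # linearized point-to-plane step: unknowns (omega, t)
    A <- cbind(P[, 2] * N[, 3] - P[, 3] * N[, 2],
               P[, 3] * N[, 1] - P[, 1] * N[, 3],
               P[, 1] * N[, 2] - P[, 2] * N[, 1],
               N)
    x <- tryCatch(solve(crossprod(A), -crossprod(A, d)),
                  error = function(e) stop("registration failed: degenerate normal system"))
    step <- rigid_transform(rotation_from_omega(x[1:3]), x[4:6])
    tf <- compose_transform(step, tf)
  }
  if (!converged)
    warning(sprintf("ICP did not converge in %d iterations (RMS %.3g mm)", it, rms))
  structure(tf, residual = rms, iterations = it, converged = converged)
}
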