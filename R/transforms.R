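#' Rigid transforms
#'
#' A rigid transform maps test-mesh coordinates into the reference frame as
#' `p -> R p + t` with `R` a proper rotation (orthonormal, det +1) and `t` a
#' translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1 (no reflections)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @param tf a `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Apply a rigid transform to points or to a labeled mesh
#'
#' @param points n x 3 matrix of coordinates (mm).
#' @param tf a `rigid_transform`.
#' @export
apply_transform <- function(points, tf) {
  points <- rbind(points)
  sweep(points %*% t(tf$rotation), 2, -tf$translation)
}

#' @rdname apply_transform
#' @param mesh a `labeled_mesh`.
#' @export
transform_mesh <- function(mesh, tf) {
  mesh$vertices <- apply_transform(mesh$vertices, tf)
  mesh
}

#' Rotation about an axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param degrees rotation angle.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, degrees) {
  axis <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Exponential map for a small rotation vector (used by the ICP update).
rotation_from_omega <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-300) return(diag(3))
  rotation_about_axis(omega / th, th * 180 / pi)
}

#' Homogeneous 4x4 matrix form of a rigid transform
#'
#' @param tf a `rigid_transform`.
#' @export
as_homogeneous <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$translation
  m
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm):\n")
  print(round(as_homogeneous(x), 6))
  res <- attr(x, "residual")
  if (!is.null(res))
    cat(sprintf("ICP residual RMS: %.3g mm after %d iterations (converged: %s)\n",
                res, attr(x, "iterations"), attr(x, "converged")))
  invisible(x)
}
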