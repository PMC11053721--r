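# Form tolerances: best-fit planes per labeled region, flatness as the sum
# of the extreme orthogonal distances on either side of the plane, and
# parallelism/perpendicularity expressed in degrees against the base plane
# (Plane Upper on the maxilla, Plane Lower on the mandible).

#' Orthogonal least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points (total least squares): the normal is the eigenvector of the
#' point covariance with the smallest eigenvalue.  When `orient` is given
#' the normal is flipped, if needed, to have a positive dot product with it
#' (the region's design normal).
#'
#' @param points a `region_point_set` or an n x 3 matrix (n >= 3,
#'   non-collinear).
#' @param orient optional length-3 orientation reference for the normal.
#' @param region optional region name (recorded; also sets the orientation
#'   class: occlusal faces are horizontal, buccal/lingual faces vertical,
#'   the base upper surface is the base/datum plane).
#' @return a `plane_fit`: `normal` (unit), `offset` (plane is
#'   `normal . p = offset`), `centroid`, `region`, `orientation_class`.
#' @export
fit_plane <- function(points, orient = NULL, region = NULL) {
  if (inherits(points, "region_point_set")) {
    if (is.null(region)) region <- points$region
    points <- points$points
  }
  points <- rbind(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  cv <- crossprod(sweep(points, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)
  # collinear/degenerate: the two smallest eigenvalues both ~ 0
  if (ev$values[2] <= max(ev$values[1], 1) * 1e-12)
    stop("degenerate point set: points are collinear")
  n <- ev$vectors[, 3]
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  structure(list(normal = n, offset = sum(n * ctr), centroid = ctr,
                 region = region,
                 orientation_class = orientation_class(region)),
            class = "plane_fit")
}

orientation_class <- function(region) {
  if (is.null(region)) return(NA_character_)
  if (region == "base:upper") return("base")
  suffix <- sub("^.*:", "", region)
  switch(suffix,
         occlusal = "horizontal",
         buccal = , lingual = "vertical",
         mesial = , distal = "vertical",
         NA_character_)
}

#' Flatness error of a region
#'
#' `flatness = x_positive + x_negative`, where `x_positive` is the distance
#' of the farthest point on the positive side of the best-fit plane and
#' `x_negative` the distance of the farthest point on the negative side
#' (each taken as 0 when no point lies on that side).
#'
#' @param fit a `plane_fit` computed from the same points.
#' @param points the points the plane was fitted to.
#' @return flatness in mm, with attributes `x_positive`, `x_negative`.
#' @export
flatness_error <- function(fit, points) {
  if (inherits(points, "region_point_set")) points <- points$points
  d <- as.numeric(rbind(points) %*% fit$normal) - fit$offset
  xp <- max(0, max(d)); xn <- max(0, -min(d))
  structure(xp + xn, x_positive = xp, x_negative = xn)
}

#' Parallelism error against the base plane
#'
#' The absolute acute angle, in degrees, between an SDC's horizontal
#' (occlusal) plane and the base plane.
#'
#' @param plane a horizontal-class `plane_fit`.
#' @param base the base-class `plane_fit` (Plane Upper / Plane Lower).
#' @return angle in degrees, in `[0, 90]`.
#' @export
parallelism_error <- function(plane, base) {
  if (!identical(plane$orientation_class, "horizontal"))
    stop("parallelism is defined for horizontal (occlusal) planes")
  if (!identical(base$orientation_class, "base"))
    stop("second argument must be the base plane")
  plane_angle(plane, base)
}

#' Perpendicularity error against the base plane
#'
#' The absolute deviation, in degrees, of the angle between an SDC's
#' vertical (buccal/lingual) plane and the base plane from 90 degrees.
#'
#' @param plane a vertical-class `plane_fit`.
#' @param base the base-class `plane_fit`.
#' @return degrees in `[0, 90]`.
#' @export
perpendicularity_error <- function(plane, base) {
  if (!identical(plane$orientation_class, "vertical"))
    stop("perpendicularity is defined for vertical (buccal/lingual) planes")
  if (!identical(base$orientation_class, "base"))
    stop("second argument must be the base plane")
  abs(plane_angle(plane, base) - 90)
}

# Acute dihedral angle between two planes, degrees in [0, 90].
plane_angle <- function(p1, p2) {
  acos(min(1, abs(sum(p1$normal * p2$normal)))) * 180 / pi
}

#' Per-region form metrics of a labeled mesh
#'
#' Fits best-fit planes to the base upper surface and the occlusal, buccal
#' and lingual faces of every SDC (sampled at `density`), and computes each
#' plane's flatness plus its parallelism (horizontal planes) or
#' perpendicularity (vertical planes) against the base plane.
#'
#' @param mesh labeled mesh to measure (reference, fixture, or a test mesh
#'   after label transfer).
#' @param reference optional labeled reference mesh supplying design normals
#'   for plane orientation (defaults to `mesh` itself).
#' @param density sampling density, points per mm^2.
#' @param seed RNG seed.
#' @return data frame, one row per plane: `region`, `orientation_class`,
#'   `flatness` (mm), `angle_metric` (`"parallelism"`/`"perpendicularity"`),
#'   `angle_error` (degrees; NA for the base row).
#' @export
form_metrics <- function(mesh, reference = mesh, density = 25, seed = 1) {
  wanted <- c("base:upper",
              grep(":(occlusal|buccal|lingual)$", names(reference$regions),
                   value = TRUE))
  missing <- setdiff(wanted, names(mesh$regions))
  if (length(missing))
    stop(sprintf("missing region(s) on mesh: %s", paste(missing, collapse = ", ")))
  sets <- sample_regions(mesh, wanted, density, seed)
  names(sets) <- wanted
  fits <- lapply(wanted, function(rn)
    fit_plane(sets[[rn]], orient = region_normal(reference, rn), region = rn))
  names(fits) <- wanted
  base <- fits[["base:upper"]]
  rows <- lapply(wanted, function(rn) {
    fl <- flatness_error(fits[[rn]], sets[[rn]])
    cls <- fits[[rn]]$orientation_class
    if (cls == "horizontal") {
      metric <- "parallelism"; ang <- parallelism_error(fits[[rn]], base)
    } else if (cls == "vertical") {
      metric <- "perpendicularity"; ang <- perpendicularity_error(fits[[rn]], base)
    } else {
      metric <- NA_character_; ang <- NA_real_
    }
    data.frame(region = rn, orientation_class = cls, flatness = as.numeric(fl),
               angle_metric = metric, angle_error = ang, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize form metrics for one jaw
#'
#' Aggregates the per-plane table of [form_metrics()]: mean and sample
#' standard deviation (n-1 denominator) of the 42 SDC flatness values, of
#' the flatness split into the 14 horizontal and 28 vertical planes, of the
#' 14 parallelism values and of the 28 perpendicularity values.  The base
#' plane's flatness is reported separately and not pooled.
#'
#' @param per_plane data frame from [form_metrics()].
#' @return a `form_summary` list of `mean`/`sd`/`n` blocks.
#' @export
summarize_form_metrics <- function(per_plane) {
  sdc <- per_plane[per_plane$region != "base:upper", ]
  horiz <- sdc[sdc$orientation_class == "horizontal", ]
  vert <- sdc[sdc$orientation_class == "vertical", ]
  if (nrow(horiz) != 14 || nrow(vert) != 28)
    stop(sprintf("expected 14 horizontal + 28 vertical SDC planes, got %d + %d",
                 nrow(horiz), nrow(vert)))
  blk <- function(x) list(mean = mean(x), sd = sd(x), n = length(x))
  structure(list(
    flatness = blk(sdc$flatness),
    flatness_horizontal = blk(horiz$flatness),
    flatness_vertical = blk(vert$flatness),
    parallelism = blk(horiz$angle_error),
    perpendicularity = blk(vert$angle_error),
    base_flatness = per_plane$flatness[per_plane$region == "base:upper"]
  ), class = "form_summary")
}
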