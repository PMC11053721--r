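# Signed surface deviations, the overall 3D deviation (RMS) and the
# 21-segment colour difference map.

#' Signed surface deviations of a test mesh from the reference
#'
#' Samples points on the named regions of the (registered) test mesh and, for
#' each point, finds the nearest point on the reference surface restricted to
#' the same regions.  The deviation is the Euclidean distance signed by the
#' side of the reference surface the test point lies on: positive on the
#' outward-normal side (material excess / expansion), negative inward
#' (contraction).
#'
#' @param test test `labeled_mesh` carrying region labels (own or
#'   transferred).
#' @param reference labeled reference mesh.
#' @param region_names regions to evaluate; default [registration_regions()].
#' @param transform `rigid_transform` mapping test into the reference frame
#'   (from [best_fit_register()], or identity for fixtures generated in the
#'   design frame).
#' @param density sampling density, points per mm^2.
#' @param seed RNG seed for sampling.
#' @return A `deviation_field`: list with `points` (sampled, reference
#'   frame), `region` per point, `deviation` (signed, mm), `n`, `rms` (mm).
#' @export
signed_deviation <- function(test, reference,
                             region_names = registration_regions(reference),
                             transform = identity_transform(),
                             density = 25, seed = 1) {
  missing <- setdiff(region_names, names(reference$regions))
  if (length(missing))
    stop(sprintf("regions not on reference: %s", paste(missing, collapse = ", ")))
  sample_from <- intersect(region_names, names(test$regions))
  if (!length(sample_from)) stop("test mesh carries none of the requested regions")
  test_r <- transform_mesh(test, transform)
  sets <- sample_regions(test_r, sample_from, density, seed)
  P <- do.call(rbind, lapply(sets, `[[`, "points"))
  if (is.null(P) || nrow(P) == 0) stop("empty sample")
  region <- rep(vapply(sets, `[[`, "", "region"),
                vapply(sets, function(s) nrow(s$points), 0L))
  ref_faces <- unlist(reference$regions[region_names], use.names = FALSE)
  hit <- cpp_closest_on_mesh(P, reference$vertices,
                             reference$faces[ref_faces, , drop = FALSE])
  N <- face_normals(reference, ref_faces)[hit$face, , drop = FALSE]
  d <- hit$distance * sign(rowSums((P - hit$closest) * N))
  structure(list(points = P, region = region, deviation = d,
                 n = length(d), rms = sqrt(mean(d^2))),
            class = "deviation_field")
}

#' Root-mean-square of a deviation field
#'
#' `RMS = sqrt(sum(d_i^2) / n)` over the signed deviations.
#'
#' @param field a `deviation_field` (or numeric vector of deviations, mm).
#' @return RMS in mm.
#' @export
rms_deviation <- function(field) {
  d <- if (inherits(field, "deviation_field")) field$deviation else as.numeric(field)
  if (length(d) == 0) stop("empty deviation field")
  sqrt(mean(d^2))
}

#' Overall 3D deviation from the two jaw values
#'
#' Aggregates the maxillary and mandibular RMS deviations into the model
#' set's overall value as their arithmetic mean (this package's documented
#' aggregation convention).
#'
#' @param rms_maxillary,rms_mandibular non-negative RMS values (any common
#'   unit).
#' @return overall value, same unit.
#' @examples
#' overall_value(47, 43)  # 45
#' @export
overall_value <- function(rms_maxillary, rms_mandibular) {
  if (rms_maxillary < 0 || rms_mandibular < 0) stop("RMS values must be >= 0")
  (rms_maxillary + rms_mandibular) / 2
}

#' Colour-map specification
#'
#' A symmetric diverging scale with an odd number of segments: the middle
#' segment spans the nominal band, each side is split into equal-width bins
#' up to the critical value, and values beyond it clamp to the end bins.
#'
#' @param segments odd number of colour segments (default 21).
#' @param critical maximum critical value, mm (band is +/- this; default 0.50).
#' @param nominal nominal value, mm (middle band is +/- this; default 0.05).
#' @return a `color_map_spec`.
#' @export
color_map_spec <- function(segments = 21, critical = 0.50, nominal = 0.05) {
  if (segments %% 2 != 1 || segments < 3) stop("segments must be odd and >= 3")
  if (!(nominal > 0 && nominal < critical))
    stop("nominal band must lie strictly inside the critical band")
  structure(list(segments = as.integer(segments), critical = critical,
                 nominal = nominal), class = "color_map_spec")
}

#' Assign deviations to colour-map bins
#'
#' Bin indices run 0..segments-1 from the most negative (contraction, blue)
#' to the most positive (expansion, red); the middle bin holds the nominal
#' band.  The assignment is monotone non-decreasing in the deviation.
#'
#' @param field a `deviation_field` or numeric vector of deviations (mm).
#' @param spec a [color_map_spec()].
#' @return integer vector of bins with attribute `legend`: data frame
#'   `bin`, `lower`, `upper` (mm) and `color` (hex).
#' @export
color_bins <- function(field, spec = color_map_spec()) {
  d <- if (inherits(field, "deviation_field")) field$deviation else as.numeric(field)
  half <- (spec$segments - 1L) / 2L
  mid <- half
  width <- (spec$critical - spec$nominal) / half
  k <- pmin(half, ceiling(pmax(abs(d) - spec$nominal, 0) / width))
  bins <- as.integer(mid + sign(d) * k)
  edges <- c(-Inf, rev(-(spec$nominal + width * seq_len(half - 1))), -spec$nominal,
             spec$nominal, spec$nominal + width * seq_len(half - 1), Inf)
  legend <- data.frame(bin = 0:(spec$segments - 1L),
                       lower = edges[seq_len(spec$segments)],
                       upper = edges[seq_len(spec$segments) + 1L],
                       color = color_ramp(spec$segments),
                       stringsAsFactors = FALSE)
  attr(bins, "legend") <- legend
  bins
}

# Blue (contraction) -> green (nominal) -> yellow -> red (expansion).
color_ramp <- function(n) {
  half <- (n - 1L) / 2L
  neg <- grDevices::colorRampPalette(c("#0000B0", "#00B0FF"))(half)
  pos <- grDevices::colorRampPalette(c("#FFFF00", "#C00000"))(half)
  c(neg, "#00C000", pos)
}
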