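# The 96-feature measurement schema: per jaw 14 MD + 14 BL + 14 CH plus six
# dental-arch feature sizes; L1-L5 and L11 live on the maxilla, L6-L10 and
# L12 on the mandible.  MD, BL and the arch dimensions are occlusal-plane
# measurements; CH is the occlusogingival one.

# (id, jaw, face pair) of the arch feature sizes.  The measurement runs from
# face `from` to face `to`; its direction is the in-plane unit vector between
# the two face centers.
.arch_features <- data.frame(
  id  = paste0("L", 1:12),
  jaw = c(rep("maxillary", 5), rep("mandibular", 5), "maxillary", "mandibular"),
  from = c("UR-FM:mesial", "UR-C:mesial",  "UL-LI:distal", "UL-C:mesial",
           "UL-FM:mesial", "LL-FM:mesial", "LL-C:mesial",  "LR-LI:distal",
           "LR-C:mesial",  "LR-FM:mesial", "UL-SM:buccal", "LL-SM:buccal"),
  to   = c("UR-SM:distal", "UR-SP:distal", "UR-LI:distal", "UL-SP:distal",
           "UL-SM:distal", "LL-SM:distal", "LL-SP:distal", "LL-LI:distal",
           "LR-SP:distal", "LR-SM:distal", "UR-SM:buccal", "LR-SM:buccal"),
  stringsAsFactors = FALSE
)

# 4 corner points (x, y) of one face of a placed SDC, from the layout table.
face_corners_2d <- function(pl, region) {
  parts <- strsplit(region, ":", fixed = TRUE)[[1]]
  i <- match(parts[1], pl$code)
  if (is.na(i)) stop(sprintf("unknown SDC '%s'", parts[1]))
  u <- c(pl$ux[i], pl$uy[i]); v <- c(pl$vx[i], pl$vy[i]); c0 <- c(pl$cx[i], pl$cy[i])
  hu <- pl$md[i] / 2; hv <- pl$bl[i] / 2
  switch(parts[2],
    mesial = rbind(c0 - hu * u - hv * v, c0 - hu * u + hv * v),
    distal = rbind(c0 + hu * u - hv * v, c0 + hu * u + hv * v),
    buccal = rbind(c0 - hu * u + hv * v, c0 + hu * u + hv * v),
    lingual = rbind(c0 - hu * u - hv * v, c0 + hu * u - hv * v),
    stop(sprintf("face '%s' has no in-plane edge", parts[2])))
}

face_center_2d <- function(pl, region) colMeans(face_corners_2d(pl, region))

#' Enumerate the 96 designed feature sizes
#'
#' Builds the measurement schema over both jaws: the mesiodistal (MD) and
#' buccolingual (BL) diameters and crown height (CH) of each of the 28 SDCs,
#' plus the twelve dental-arch dimensions L1-L12 measured between named SDC
#' faces.  Designed values for MD/BL/CH are the crown dimensions of the spec;
#' L1-L12 designed values are derived deterministically from the arch layout
#' (supporting-plane span between the two defining faces along the in-plane
#' direction connecting them), so the schema is self-consistent with the
#' virtual caliper on the generated reference meshes.
#'
#' @param spec_max maxillary `model_spec`.
#' @param spec_mand mandibular `model_spec`.
#' @return A `feature_schema` data frame with one row per feature: `id`
#'   (e.g. `"MD-UL-FM"`, `"CH-LR-SM"`, `"L3"`), `jaw`, `axis_class`
#'   (`"occlusal-plane"` or `"occlusogingival"`), `region_a`/`region_b`
#'   (defining surface pair; the caliper spans from the extreme of `b` to
#'   the extreme of `a`), `ux,uy,uz` (unit measurement direction in the
#'   design frame) and `designed` (mm).
#' @examples
#' schema <- enumerate_feature_sizes(default_spec("maxillary"),
#'                                   default_spec("mandibular"))
#' nrow(schema)  # 96
#' @export
enumerate_feature_sizes <- function(spec_max = default_spec("maxillary"),
                                    spec_mand = default_spec("mandibular")) {
  if (spec_max$jaw != "maxillary" || spec_mand$jaw != "mandibular")
    stop("arguments must be the maxillary and mandibular specs, in that order")
  pls <- list(maxillary = sdc_placements(spec_max),
              mandibular = sdc_placements(spec_mand))
  rows <- list()
  for (jaw in names(pls)) {
    pl <- pls[[jaw]]
    for (i in seq_len(nrow(pl))) {
      code <- pl$code[i]
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("MD-", code), jaw = jaw, axis_class = "occlusal-plane",
        region_a = paste0(code, ":distal"), region_b = paste0(code, ":mesial"),
        ux = pl$ux[i], uy = pl$uy[i], uz = 0, designed = pl$md[i],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("BL-", code), jaw = jaw, axis_class = "occlusal-plane",
        region_a = paste0(code, ":buccal"), region_b = paste0(code, ":lingual"),
        ux = pl$vx[i], uy = pl$vy[i], uz = 0, designed = pl$bl[i],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("CH-", code), jaw = jaw, axis_class = "occlusogingival",
        region_a = paste0(code, ":occlusal"), region_b = paste0(code, ":gingival"),
        ux = 0, uy = 0, uz = 1, designed = pl$ch[i],
        stringsAsFactors = FALSE)
    }
    af <- .arch_features[.arch_features$jaw == jaw, ]
    for (k in seq_len(nrow(af))) {
      u <- face_center_2d(pl, af$to[k]) - face_center_2d(pl, af$from[k])
      u <- u / sqrt(sum(u^2))
      span <- max(face_corners_2d(pl, af$to[k]) %*% u) -
              min(face_corners_2d(pl, af$from[k]) %*% u)
      rows[[length(rows) + 1L]] <- data.frame(
        id = af$id[k], jaw = jaw, axis_class = "occlusal-plane",
        region_a = af$to[k], region_b = af$from[k],
        ux = u[1], uy = u[2], uz = 0, designed = span,
        stringsAsFactors = FALSE)
    }
  }
  schema <- do.call(rbind, rows)
  rownames(schema) <- NULL
  class(schema) <- c("feature_schema", "data.frame")
  schema
}
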