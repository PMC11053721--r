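# Crown dimension defaults for the structurized dental model, from published
# mean crown dimensions of the Chinese population (mm).
.tooth_types <- c("central incisor", "lateral incisor", "canine",
                  "first premolar", "second premolar", "first molar",
                  "second molar")
.tooth_codes <- c("CI", "LI", "C", "FP", "SP", "FM", "SM")

.sdc_defaults <- list(
  maxillary = data.frame(
    tooth_type = .tooth_types, code = .tooth_codes,
    md = c(8, 7, 8, 7, 7, 10, 9),
    bl = c(7, 6, 8, 9, 9, 11, 11),
    ch = c(10, 9, 11, 10, 10, 8, 5),
    stringsAsFactors = FALSE
  ),
  mandibular = data.frame(
    tooth_type = .tooth_types, code = .tooth_codes,
    md = c(5, 6, 7, 7, 7, 11, 11),
    bl = c(6, 6, 7, 8, 8, 10, 10),
    ch = c(8, 8, 8, 7, 7, 10, 12),
    stringsAsFactors = FALSE
  )
)

#' Default parametric specification of a structurized dental model
#'
#' Returns the full parametric description of one jaw's structurized model:
#' the simulated dental crown (SDC) dimensions — mesiodistal diameter (MD),
#' buccolingual diameter (BL) and crown height (CH) of each of the seven
#' tooth types, mirrored left/right into 14 SDCs — plus the arch-layout and
#' horseshoe-base parameters.  Crown dimensions default to the published
#' population crown measurements the structurized model is dimensioned from;
#' the arch layout (parabolic arch, 2 mm minimal clearance between adjacent
#' SDC footprints, 5 mm base thickness) is this package's documented default,
#' since trueness metrics depend only on designed-vs-measured consistency.
#'
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @return A `model_spec`: list with `jaw`, `sdc` (data frame `tooth_type`,
#'   `code`, `md`, `bl`, `ch`, mm), and `arch` (list: `curvature` of the
#'   parabolic arch mm^-1, `gap` mm, `base_thickness` mm, `base_margin` mm,
#'   `end_margin` mm).
#' @examples
#' spec <- default_spec("maxillary")
#' subset(spec$sdc, code == "FM") # first molar: MD 10, BL 11, CH 8
#' @export
default_spec <- function(jaw = c("maxillary", "mandibular")) {
  jaw <- match.arg(jaw)
  structure(list(
    jaw = jaw,
    units = "mm",
    sdc = .sdc_defaults[[jaw]],
    arch = list(
      curvature = 0.035,     # parabola y = -curvature * x^2
      gap = 2,               # minimal clearance between adjacent SDC footprints
      base_thickness = 5,    # horseshoe base height; base upper surface at z = 5
      base_margin = 2.5,     # strip half-width beyond the widest SDC footprint
      end_margin = 4         # strip extension beyond the last molar
    ),
    placements = NULL        # optional layout override (see sdc_placements)
  ), class = "model_spec")
}

#' Validate a model specification
#'
#' Checks the `model_spec` invariants: strictly positive crown dimensions,
#' seven tooth types, a positive inter-SDC gap and base thickness.
#'
#' @param spec a `model_spec`.
#' @return `spec`, invisibly; stops on violation.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "model_spec")) stop("not a model_spec")
  if (!spec$jaw %in% c("maxillary", "mandibular")) stop("invalid jaw name")
  s <- spec$sdc
  if (nrow(s) != 7L || !identical(s$code, .tooth_codes))
    stop("spec must describe the seven tooth types CI, LI, C, FP, SP, FM, SM")
  if (any(!is.finite(c(s$md, s$bl, s$ch))) || any(c(s$md, s$bl, s$ch) <= 0))
    stop("all SDC dimensions (md, bl, ch) must be strictly positive")
  if (spec$arch$gap <= 0) stop("inter-SDC gap must be positive")
  if (spec$arch$base_thickness <= 0) stop("base thickness must be positive")
  invisible(spec)
}

# UR/UL for the maxilla, LR/LL for the mandible.
side_prefixes <- function(jaw) {
  if (jaw == "maxillary") c(right = "UR", left = "UL") else c(right = "LR", left = "LL")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Structurized dental model spec: %s jaw (units mm)\n", x$jaw))
  print(x$sdc, row.names = FALSE)
  cat(sprintf("Arch: parabolic (curvature %.3f/mm), gap %.1f mm, base %.1f mm thick\n",
              x$arch$curvature, x$arch$gap, x$arch$base_thickness))
  invisible(x)
}
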