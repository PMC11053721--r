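# Linear dimensional errors: virtual-caliper measurement of the 96 feature
# sizes, relative errors, occlusal-plane / occlusogingival aggregation, and
# intraclass correlation for repeated measurements.

#' Virtual caliper measurement of one feature size
#'
#' Mimics rigid caliper jaws: two parallel supporting planes, both
#' orthogonal to the feature's design measurement direction, each contacting
#' the extreme point of its defining region along that direction.  The
#' measured value is the distance between the planes, i.e.
#' `max(u . p, p in region_a) - min(u . p, p in region_b)`.
#'
#' @param mesh a `labeled_mesh` (registered into the design frame).
#' @param feature one schema row from [enumerate_feature_sizes()] (or any
#'   list with `region_a`, `region_b`, `ux`, `uy`, `uz`).
#' @return measured length in mm.  A negative span (regions overlapping
#'   along the axis) is returned as-is with a warning flagging the
#'   measurement failure.
#' @export
virtual_caliper <- function(mesh, feature) {
  u <- c(feature$ux, feature$uy, feature$uz)
  pa <- region_vertices(mesh, feature$region_a)
  pb <- region_vertices(mesh, feature$region_b)
  span <- max(pa %*% u) - min(pb %*% u)
  if (span < 0)
    warning(sprintf("measurement failure for %s: negative span (regions overlap along the axis)",
                    feature$id))
  span
}

#' Relative error of a measured feature size
#'
#' `(x2 - x1) / x1 * 100`: positive for an enlargement of the printed
#' dimension, negative for a shrinkage.
#'
#' @param x1 designed dimension, mm (> 0).
#' @param x2 measured dimension, mm.
#' @return relative error in percent.
#' @examples
#' relative_error(10, 10.002)  # 0.02 (% <=> 2 um on a 10 mm object)
#' @export
relative_error <- function(x1, x2) {
  if (any(x1 <= 0)) stop("designed dimension x1 must be > 0")
  (x2 - x1) / x1 * 100
}

#' Measure all schema features on a mesh
#'
#' @param mesh labeled mesh to measure.
#' @param schema a `feature_schema`.
#' @param jaw optional jaw filter (`"maxillary"`/`"mandibular"`).
#' @return the schema rows with `measured` (mm) and `relative_error` (%)
#'   columns appended.
#' @export
measure_features <- function(mesh, schema, jaw = NULL) {
  if (!is.null(jaw)) schema <- schema[schema$jaw == jaw, ]
  schema$measured <- vapply(seq_len(nrow(schema)), function(i)
    virtual_caliper(mesh, schema[i, ]), 0)
  schema$relative_error <- relative_error(schema$designed, schema$measured)
  schema
}

#' Aggregate linear errors for one jaw
#'
#' Mean and sample standard deviation of the relative errors of the 34
#' occlusal-plane dimensions (14 MD + 14 BL + 6 arch dimensions) and the 14
#' occlusogingival dimensions (CH): the occlusal plane error and the
#' occlusogingival direction error, i.e. the printer's X-Y plane and Z-axis
#' errors.
#'
#' @param features measured feature table from [measure_features()] for one
#'   jaw.
#' @param jaw jaw name the features must belong to.
#' @return a `linear_summary`: lists `occlusal_plane` and `occlusogingival`
#'   with `mean`, `sd` (percent) and `n`.
#' @export
summarize_linear <- function(features, jaw = c("maxillary", "mandibular")) {
  jaw <- match.arg(jaw)
  features <- features[features$jaw == jaw, ]
  expected <- enumerate_feature_sizes()
  expected <- expected$id[expected$jaw == jaw]
  missing <- setdiff(expected, features$id)
  if (length(missing))
    stop(sprintf("incomplete feature set for the %s jaw; missing: %s",
                 jaw, paste(missing, collapse = ", ")))
  occ <- features$relative_error[features$axis_class == "occlusal-plane"]
  og <- features$relative_error[features$axis_class == "occlusogingival"]
  stopifnot(length(occ) == 34, length(og) == 14)
  structure(list(
    occlusal_plane = list(mean = mean(occ), sd = sd(occ), n = length(occ)),
    occlusogingival = list(mean = mean(og), sd = sd(og), n = length(og))
  ), class = "linear_summary")
}

#' Average repeated measurements
#'
#' Linear measurements are repeated (five times in the reference protocol)
#' and averaged per feature.
#'
#' @param measurements numeric vector of repeats for one feature, or a
#'   matrix/data frame with one row per feature and one column per repeat.
#' @return per-feature arithmetic mean.
#' @export
average_repeats <- function(measurements) {
  if (is.matrix(measurements) || is.data.frame(measurements))
    rowMeans(as.matrix(measurements))
  else mean(as.numeric(measurements))
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' ICC(2,1): single-measure, absolute-agreement ICC from the two-way ANOVA
#' mean squares of a complete features x raters (or repetitions) matrix,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.  Used both for
#' intra-examiner (columns = repeated sessions) and inter-examiner (columns
#' = examiners) reliability.
#'
#' @param measurements complete numeric matrix, rows = features, columns =
#'   raters/repetitions; no missing cells.
#' @param mode `"intra"` or `"inter"` (annotation only; the estimator is the
#'   same).
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(measurements, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("ICC requires a complete matrix (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 features and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
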