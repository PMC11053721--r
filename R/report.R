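# Pipeline assembly and report generation: register -> label transfer ->
# deviation -> form metrics -> virtual caliper -> summaries, with report
# output mirroring the standard trueness-report layout (per-jaw and overall
# RMS; flatness/parallelism/perpendicularity; occlusal-plane and
# occlusogingival linear errors; colour-map export).

#' Default evaluation configuration
#'
#' @return list of tunables: sampling densities (points per mm^2) for
#'   registration, deviation and form-metric sampling; ICP settings; label
#'   transfer cutoff (mm); colour-map spec; RNG seed.
#' @export
default_config <- function() {
  list(
    units = "mm",
    seed = 1L,
    densities = list(registration = 5, deviation = 25, form = 25),
    registration = list(max_iter = 200L, tol = 1e-7),
    label_cutoff = 0.5,
    colormap = list(segments = 21L, critical = 0.50, nominal = 0.05)
  )
}

#' Read a configuration file (YAML or JSON), merged over the defaults
#'
#' @param path config file; keys missing from it keep their defaults.
#' @return config list.
#' @export
read_config <- function(path) {
  if (is.null(path)) return(default_config())
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Evaluate one test model against its reference
#'
#' Runs the single-jaw evaluation pipeline: best-fit registration (unless
#' `register = "none"`, for fixtures already in the design frame), region
#' label transfer when the test mesh is unlabeled, signed-deviation
#' analysis with RMS and colour bins, per-plane form metrics, and
#' virtual-caliper measurement of the jaw's 48 feature sizes.
#'
#' @param reference labeled reference mesh.
#' @param test test mesh (labeled or not).
#' @param schema feature schema from [enumerate_feature_sizes()].
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @param config configuration list (see [default_config()]).
#' @param register `"icp"` to run [best_fit_register()], `"none"` to take
#'   the meshes as already aligned.
#' @return a `jaw_evaluation` list: `transform`, `registration`
#'   (residual/iterations/converged), `deviation_rms_um`, `deviation`
#'   field, `color_bins`, `form` (per-plane), `form_summary`, `features`,
#'   `linear_summary`.
#' @export
evaluate_model <- function(reference, test, schema, jaw, config = default_config(),
                           register = c("icp", "none")) {
  register <- match.arg(register)
  if (register == "icp") {
    tf <- best_fit_register(test, reference,
                            options = list(density = config$densities$registration,
                                           max_iter = config$registration$max_iter,
                                           tol = config$registration$tol,
                                           seed = config$seed))
    if (!attr(tf, "converged"))
      warning(sprintf("registration of the %s model did not converge", jaw))
  } else {
    tf <- structure(identity_transform(), residual = NA_real_,
                    iterations = 0L, converged = TRUE)
  }
  test_reg <- transform_mesh(test, tf)
  if (!all(registration_regions(reference) %in% names(test_reg$regions)))
    test_reg <- transfer_labels(reference, test_reg, cutoff = config$label_cutoff)

  dev <- signed_deviation(test_reg, reference,
                          density = config$densities$deviation,
                          seed = config$seed)
  cmspec <- color_map_spec(config$colormap$segments, config$colormap$critical,
                           config$colormap$nominal)
  bins <- color_bins(dev, cmspec)

  form <- form_metrics(test_reg, reference,
                       density = config$densities$form, seed = config$seed)
  features <- measure_features(test_reg, schema, jaw = jaw)

  structure(list(
    jaw = jaw,
    transform = tf,
    registration = list(residual = attr(tf, "residual"),
                        iterations = attr(tf, "iterations"),
                        converged = attr(tf, "converged"),
                        mode = register),
    deviation = dev,
    deviation_rms_um = dev$rms * 1000,
    color_bins = bins,
    form = form,
    form_summary = summarize_form_metrics(form),
    features = features,
    linear_summary = summarize_linear(features, jaw)
  ), class = "jaw_evaluation")
}

#' Assemble a trueness report over both jaws
#'
#' @param eval_max,eval_mand `jaw_evaluation` objects (either may be NULL;
#'   metrics needing both jaws are then marked skipped).
#' @param config the configuration used.
#' @param inputs named character vector of input files, for provenance.
#' @return a `trueness_report`.
#' @export
trueness_report <- function(eval_max = NULL, eval_mand = NULL,
                            config = default_config(), inputs = character()) {
  if (is.null(eval_max) && is.null(eval_mand)) stop("no evaluations supplied")
  jaws <- Filter(Negate(is.null), list(maxillary = eval_max, mandibular = eval_mand))
  overall_um <- if (length(jaws) == 2)
    overall_value(eval_max$deviation_rms_um, eval_mand$deviation_rms_um)
  else NA_real_
  structure(list(
    jaws = jaws,
    overall_rms_um = overall_um,
    provenance = list(inputs = as.list(inputs),
                      seed = config$seed,
                      config_hash = config_hash(config),
                      tool = paste0("truedent ",
                                    as.character(utils::packageVersion("truedent")))),
    config = config
  ), class = "trueness_report")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Display rounding mirroring the report layout: RMS in integer um, mm and
# degree metrics to 3 decimals, percentages to 2.
report_display <- function(report) {
  fmt_blk <- function(b, digits) list(mean = round(b$mean, digits),
                                      sd = round(b$sd, digits), n = b$n)
  jaws <- lapply(report$jaws, function(ev) list(
    overall_3d_deviation_um = round(ev$deviation_rms_um),
    flatness_mm = fmt_blk(ev$form_summary$flatness, 3),
    flatness_horizontal_mm = fmt_blk(ev$form_summary$flatness_horizontal, 3),
    flatness_vertical_mm = fmt_blk(ev$form_summary$flatness_vertical, 3),
    parallelism_deg = fmt_blk(ev$form_summary$parallelism, 3),
    perpendicularity_deg = fmt_blk(ev$form_summary$perpendicularity, 3),
    occlusal_plane_error_pct = fmt_blk(ev$linear_summary$occlusal_plane, 2),
    occlusogingival_error_pct = fmt_blk(ev$linear_summary$occlusogingival, 2)
  ))
  list(jaws = jaws,
       overall_3d_deviation_um = if (is.na(report$overall_rms_um)) "skipped"
                                 else round(report$overall_rms_um))
}

#' @export
print.trueness_report <- function(x, ...) {
  disp <- report_display(x)
  for (jaw in names(disp$jaws)) {
    d <- disp$jaws[[jaw]]
    cat(sprintf("%s model:\n", jaw))
    cat(sprintf("  overall 3D deviation: %d um\n", d$overall_3d_deviation_um))
    cat(sprintf("  flatness: %.3f +/- %.3f mm (horizontal %.3f, vertical %.3f)\n",
                d$flatness_mm$mean, d$flatness_mm$sd,
                d$flatness_horizontal_mm$mean, d$flatness_vertical_mm$mean))
    cat(sprintf("  parallelism: %.3f +/- %.3f deg; perpendicularity: %.3f +/- %.3f deg\n",
                d$parallelism_deg$mean, d$parallelism_deg$sd,
                d$perpendicularity_deg$mean, d$perpendicularity_deg$sd))
    cat(sprintf("  occlusal plane error: %.2f +/- %.2f %%; occlusogingival: %.2f +/- %.2f %%\n",
                d$occlusal_plane_error_pct$mean, d$occlusal_plane_error_pct$sd,
                d$occlusogingival_error_pct$mean, d$occlusogingival_error_pct$sd))
  }
  cat(sprintf("overall value (both jaws): %s um\n",
              format(disp$overall_3d_deviation_um)))
  invisible(x)
}

#' Write a trueness report to disk
#'
#' Writes `report.json` (full-precision values plus the display-rounded
#' block and provenance), per-jaw feature CSVs, per-plane form-metric CSVs,
#' a deviation CSV (point, deviation, bin) and a colour-map point cloud as
#' ASCII PLY with per-vertex colour.
#'
#' @param report a `trueness_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    display = report_display(report),
    raw = lapply(report$jaws, function(ev) list(
      registration = ev$registration,
      transform = as_homogeneous(ev$transform),
      deviation_rms_um = ev$deviation_rms_um,
      form_summary = unclass(ev$form_summary),
      linear_summary = unclass(ev$linear_summary))),
    overall_rms_um = report$overall_rms_um,
    provenance = report$provenance,
    config = report$config)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", na = "null")
  for (jaw in names(report$jaws)) {
    ev <- report$jaws[[jaw]]
    write.csv(ev$features[, c("id", "axis_class", "designed", "measured",
                              "relative_error")],
              file.path(dir, sprintf("features_%s.csv", jaw)), row.names = FALSE)
    write.csv(ev$form, file.path(dir, sprintf("form_%s.csv", jaw)),
              row.names = FALSE)
    dev_df <- data.frame(x = ev$deviation$points[, 1],
                         y = ev$deviation$points[, 2],
                         z = ev$deviation$points[, 3],
                         region = ev$deviation$region,
                         deviation_mm = ev$deviation$deviation,
                         bin = as.integer(ev$color_bins))
    write.csv(dev_df, file.path(dir, sprintf("deviation_%s.csv", jaw)),
              row.names = FALSE)
    write_color_ply(ev, file.path(dir, sprintf("colormap_%s.ply", jaw)))
  }
  invisible(dir)
}

# Colour-map point cloud: sampled deviation points coloured by bin.
write_color_ply <- function(ev, path) {
  legend <- attr(ev$color_bins, "legend")
  rgb <- t(grDevices::col2rgb(legend$color[match(as.integer(ev$color_bins),
                                                 legend$bin)]))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(ev$deviation$points)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                     ev$deviation$points[, 1], ev$deviation$points[, 2],
                     ev$deviation$points[, 3], rgb[, 1], rgb[, 2], rgb[, 3]), con)
  invisible(path)
}
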