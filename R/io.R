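# File formats and configuration. All quantities are SI internally; CSV
# headers carry unit suffixes (um, um_s, px) and are converted at the
# boundary.

#' Calibration configuration
#'
#' Validated bundle of the physical and protocol parameters shared by the
#' pipeline stages.
#'
#' @param viscosity Medium dynamic viscosity (Pa s).
#' @param bead_radius Bead radius (m).
#' @param height Sphere-centre-to-wall distance (m), > `bead_radius`; must
#'   be given explicitly — unbounded fluid is never assumed silently.
#' @param pixel_size Physical pixel size (m/px).
#' @param tilt Force-to-cantilever-normal angle (rad).
#' @param n_medium,n_sphere Refractive indices.
#' @param trap_offset Trap-to-bead-centre parking offset (m); default the
#'   bead radius.
#' @param geometry Cantilever geometry: `"rectangular"`, `"v_shape"`, or
#'   `"auto"`.
#' @param rel_tol Linear-range residual tolerance.
#' @param seed Integer seed for stochastic steps.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(viscosity = 1e-3,
                               bead_radius = 7.5e-6,
                               height = 3 * bead_radius,
                               pixel_size = 30e-9,
                               tilt = 0,
                               n_medium = 1.33,
                               n_sphere = 1.45,
                               trap_offset = bead_radius,
                               geometry = c("auto", "rectangular", "v_shape"),
                               rel_tol = 0.05,
                               seed = 1L) {
  geometry <- match.arg(geometry)
  assert_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  assert_number(bead_radius, "bead_radius", lower = 0, strict_lower = TRUE)
  assert_number(height, "height")
  if (height <= bead_radius)
    tz_domain_error("height must exceed bead_radius")
  assert_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  assert_number(tilt, "tilt", lower = 0, upper = pi / 2, strict_upper = TRUE)
  assert_number(n_medium, "n_medium", lower = 1)
  assert_number(n_sphere, "n_sphere", lower = 1)
  assert_number(trap_offset, "trap_offset", lower = 0)
  assert_number(rel_tol, "rel_tol", lower = 0, strict_lower = TRUE)
  assert_number(seed, "seed")
  structure(list(viscosity = viscosity, bead_radius = bead_radius,
                 height = height, pixel_size = pixel_size, tilt = tilt,
                 n_medium = n_medium, n_sphere = n_sphere,
                 trap_offset = trap_offset, geometry = geometry,
                 rel_tol = rel_tol, seed = as.integer(seed)),
            class = "calibration_config")
}

#' Read a calibration configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' [calibration_config()] defaults.
#'
#' @param path YAML file.
#' @return A `calibration_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) tz_parse_error(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(calibration_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    tz_parse_error(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(calibration_config, vals)
}

check_numeric_column <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x) || is.factor(x)) {
    x2 <- suppressWarnings(as.numeric(as.character(x)))
    bad <- which(is.na(x2) & !is.na(x))
    if (length(bad))
      tz_parse_error(sprintf(
        "%s: non-numeric value '%s' in column '%s', row %d (decimal commas are not accepted)",
        path, as.character(x)[bad[1]], col, bad[1]))
    x <- x2
  }
  if (anyNA(x))
    tz_parse_error(sprintf("%s: missing value in column '%s', row %d",
                           path, col, which(is.na(x))[1]))
  x
}

#' Read drag-calibration sweeps from CSV
#'
#' Expects columns `power_percent`, `stage_speed_um_s`, `displacement_um`
#' (micrometre units in the file, converted to SI on read) and groups rows
#' by power.
#'
#' @param path CSV file.
#' @param conditions A [drag_conditions()] template (viscosity, radius,
#'   height).
#' @return List of [drag_sweep()]s, sorted by power.
#' @export
read_sweeps <- function(path, conditions) {
  if (!file.exists(path)) tz_parse_error(sprintf("sweep file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) tz_parse_error(
                   sprintf("%s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0) tz_parse_error(sprintf("%s: empty sweep file", path))
  need <- c("power_percent", "stage_speed_um_s", "displacement_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    tz_parse_error(sprintf("%s: missing column(s): %s", path,
                           paste(missing_cols, collapse = ", ")))
  for (col in need) df[[col]] <- check_numeric_column(df, col, path)
  # split() on a numeric key orders groups by the numeric value
  lapply(split(df, df$power_percent),
         function(g) drag_sweep(
           g$power_percent[1],
           data.frame(speed = g$stage_speed_um_s * 1e-6,
                      displacement = g$displacement_um * 1e-6),
           conditions))
}

#' Write drag sweeps to CSV
#'
#' Inverse of [read_sweeps()] (micrometre units in the file).
#'
#' @param sweeps List of [drag_sweep()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  rows <- do.call(rbind, lapply(sweeps, function(s)
    data.frame(power_percent = s$power,
               stage_speed_um_s = s$records$speed * 1e6,
               displacement_um = s$records$displacement * 1e6)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a grayscale image frame
#'
#' TIFF (via the tiff package) or PNG (via the png package, if installed);
#' multi-channel images are averaged to grayscale. Matrix rows map to the
#' microscope Z axis, columns to Y (see [bead_image()]).
#'
#' @param path Image file (.tif/.tiff/.png).
#' @param pixel_size Physical pixel size (m/px).
#' @return A [bead_image()].
#' @export
read_frame <- function(path, pixel_size) {
  if (!file.exists(path)) tz_parse_error(sprintf("frame not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      tz_parse_error("the png package is required to read PNG frames")
    png::readPNG(path)
  } else tz_parse_error(sprintf("unsupported frame format: .%s", ext))
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  bead_image(px, pixel_size)
}

#' Write a bead image as a grayscale TIFF
#'
#' Intensities are clamped to `[0, 1]`.
#'
#' @param image A [bead_image()] or numeric matrix.
#' @param path Output path (.tif).
#' @return `path`, invisibly.
#' @export
write_frame <- function(image, path) {
  px <- if (inherits(image, "bead_image")) image$pixels else image
  tiff::writeTIFF(pmin(pmax(px, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

no_nan <- function(x, where = "report") {
  if (is.list(x)) {
    for (el in x) no_nan(el, where)
  } else if (is.numeric(x) && any(is.nan(x)))
    tz_domain_error(sprintf("NaN is forbidden in a written %s", where))
  invisible(TRUE)
}

drop_na_fields <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_na_fields)
  x[!vapply(x, function(el)
    length(el) == 1 && !is.list(el) && is.na(el), logical(1))]
}

#' Write a schema-versioned JSON report
#'
#' Serializes model objects (trap models, cantilever models, arbitrary
#' result lists) with a schema tag so reports are self-describing and
#' round-trip losslessly through [read_report()]. `NaN` values are
#' rejected; `NA` fields are dropped.
#'
#' @param x A `trap_model`, `cantilever_model`, or plain list.
#' @param path Output JSON path.
#' @param kind Payload kind recorded in the report (defaults to the class).
#' @param seed Optional seed to record for reproducibility.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, kind = NULL, seed = NULL) {
  if (is.null(kind))
    kind <- if (inherits(x, "trap_model")) "trap_model"
      else if (inherits(x, "cantilever_model")) "cantilever_model"
      else "result"
  no_nan(unclass(x))
  payload <- drop_na_fields(unclass(x))
  report <- list(schema = "tweezercal/report", schema_version = 1L,
                 kind = kind, seed = seed, payload = payload)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' Restores `trap_model` and `cantilever_model` classes.
#'
#' @param path JSON report path.
#' @return The payload, classed when its kind is a known model.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) tz_parse_error(sprintf("report not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema) || !identical(rep$schema, "tweezercal/report"))
    tz_parse_error(sprintf("%s is not a tweezercal report", path))
  payload <- rep$payload
  if (identical(rep$kind, "trap_model")) {
    payload$linear_range <- stats::setNames(unlist(payload$linear_range),
                                            c("P_min", "P_max"))
    class(payload) <- "trap_model"
  } else if (identical(rep$kind, "cantilever_model")) {
    class(payload) <- "cantilever_model"
  }
  payload
}
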