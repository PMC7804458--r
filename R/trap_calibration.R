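#' Drag sweep at one laser power
#'
#' One trap-stiffness calibration sweep: the stage oscillates (sawtooth
#' protocol, alternating direction) at known speeds while the trapped bead's
#' displacement from the trap centre is recorded.
#'
#' @param power Laser power as percent of maximum, in `(0, 100]`.
#' @param records Data frame with numeric columns `speed` (m/s, signed) and
#'   `displacement` (m, signed); at least 4 rows.
#' @param conditions A [drag_conditions()] template (its `speed` field is
#'   ignored; each record supplies its own).
#' @return An object of class `drag_sweep`.
#' @export
drag_sweep <- function(power, records, conditions) {
  assert_number(power, "power", lower = 0, upper = 100, strict_lower = TRUE)
  stopifnot(inherits(conditions, "drag_conditions"))
  if (!is.data.frame(records) ||
      !all(c("speed", "displacement") %in% names(records)))
    tz_domain_error("records must be a data frame with columns speed, displacement")
  if (nrow(records) < 4)
    tz_insufficient_data("a drag sweep needs at least 4 (speed, displacement) records")
  if (!all(vapply(records[c("speed", "displacement")], is.numeric, TRUE)))
    tz_domain_error("speed and displacement must be numeric")
  structure(list(power = power,
                 records = records[c("speed", "displacement")],
                 conditions = conditions),
            class = "drag_sweep")
}

#' Trap stiffness from one drag sweep
#'
#' Converts each record's stage speed into a wall-corrected Stokes drag
#' force and regresses force on bead displacement; the slope is the trap
#' stiffness at that power. Because the sawtooth protocol makes the bead sit
#' at opposite edges of the trap in the two stage directions, the fit uses a
#' direction-specific free intercept (one intercept per sign of the speed)
#' so the finite trap width cannot bias the slope; for one-directional
#' sweeps this reduces to an ordinary free-intercept fit. A through-origin
#' slope and the plain pooled free-intercept slope are also reported for
#' transparency.
#'
#' @param sweep A [drag_sweep()].
#' @return An object of class `stiffness_point`: a list with `power`,
#'   `stiffness` (N/m), `stderr` (N/m), `r_squared`, `n`,
#'   `stiffness_through_origin`, `stiffness_pooled`, and `nonpositive`
#'   (flag, `TRUE` when the fitted slope is not positive — reported, not an
#'   error).
#' @export
stiffness_from_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "drag_sweep"))
  rec <- sweep$records
  if (nrow(rec) < 4)
    tz_insufficient_data("at least 4 records are required")
  if (stats::sd(rec$displacement) == 0)
    tz_degenerate_error("all displacements identical: degenerate regressor")
  cond <- sweep$conditions
  force <- vapply(rec$speed, function(v)
    drag_force(drag_conditions(cond$viscosity, cond$radius, cond$height, v)),
    numeric(1))
  dirs <- factor(sign(rec$speed))
  fit <- if (nlevels(dirs) > 1)
    stats::lm(force ~ rec$displacement + dirs)
  else
    stats::lm(force ~ rec$displacement)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  slope <- unname(stats::coef(fit)["rec$displacement"])
  se <- sm$coefficients["rec$displacement", "Std. Error"]
  pooled <- unname(stats::coef(stats::lm(force ~ rec$displacement))[2])
  origin <- unname(stats::coef(stats::lm(force ~ rec$displacement - 1))[1])
  structure(list(power = sweep$power,
                 stiffness = slope,
                 stderr = se,
                 r_squared = sm$r.squared,
                 n = nrow(rec),
                 stiffness_pooled = pooled,
                 stiffness_through_origin = origin,
                 nonpositive = !is.na(slope) && slope <= 0),
            class = "stiffness_point")
}

#' Collect stiffness points into a table
#'
#' @param points List of `stiffness_point` objects (or an already-formed
#'   data frame with columns `power`, `stiffness`, and optionally `stderr`).
#' @return Data frame sorted by power.
#' @export
stiffness_table <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("power", "stiffness") %in% names(points)))
      tz_domain_error("stiffness table needs columns power, stiffness")
    if (is.null(points$stderr)) points$stderr <- NA_real_
    tab <- points[c("power", "stiffness", "stderr")]
  } else {
    tab <- do.call(rbind, lapply(points, function(p)
      data.frame(power = p$power, stiffness = p$stiffness, stderr = p$stderr)))
  }
  tab[order(tab$power), , drop = FALSE]
}

#' Detect the linear power range of the trap
#'
#' The trap stiffness grows linearly with laser power only up to a
#' saturation knee; calibration points beyond it must be discarded. The
#' knee is located by a longest-prefix residual test: starting from the
#' lowest power, the longest run of points for which an ordinary
#' least-squares line leaves every relative residual within `rel_tol` is
#' retained, and the last included power is the upper bound of the linear
#' range.
#'
#' @param points Stiffness table ([stiffness_table()]) or list of
#'   `stiffness_point`s, >= 4 points.
#' @param rel_tol Maximum allowed `|residual| / fitted` for every point in
#'   the prefix (default 0.05).
#' @return Numeric vector `c(P_min, P_max)` in percent.
#' @export
detect_linear_range <- function(points, rel_tol = 0.05) {
  tab <- stiffness_table(points)
  n <- nrow(tab)
  if (n < 4)
    tz_insufficient_data("linear-range detection needs at least 4 stiffness points")
  assert_number(rel_tol, "rel_tol", lower = 0, strict_lower = TRUE)
  for (m in seq(n, 4)) {
    sub <- tab[seq_len(m), ]
    fit <- stats::lm(stiffness ~ power, data = sub)
    rel <- abs(stats::resid(fit)) / abs(stats::fitted(fit))
    if (all(is.finite(rel)) && all(rel <= rel_tol))
      return(c(P_min = sub$power[1], P_max = sub$power[m]))
  }
  tz_calibration_failure(
    "no prefix of >= 4 stiffness points is linear within rel_tol")
}

#' Fit the stiffness-versus-power line of the trap
#'
#' Least-squares line of trap stiffness on laser power restricted to the
#' linear range; points outside the range are kept in the returned table
#' but do not contribute to the fit. When every in-range point carries a
#' finite positive standard error (as [stiffness_from_sweep()] provides),
#' the fit is inverse-variance weighted — per-power stiffness estimates are
#' markedly heteroscedastic (their error grows with the stiffness itself),
#' and ignoring that miscalibrates the slope's confidence interval.
#' Without usable errors the fit is plain OLS.
#'
#' @param points Stiffness table or list of `stiffness_point`s.
#' @param range Numeric `c(P_min, P_max)`; when `NULL`, found with
#'   [detect_linear_range()].
#' @param rel_tol Passed to [detect_linear_range()] when `range` is `NULL`.
#' @return An object of class `trap_model` with fields `slope`, `intercept`,
#'   their standard errors `slope_se`/`intercept_se`, residual degrees of
#'   freedom `df`, `linear_range`, `r_squared`, `weighted`, and `points`
#'   (table with an `in_range` flag).
#' @export
fit_stiffness_vs_power <- function(points, range = NULL, rel_tol = 0.05) {
  tab <- stiffness_table(points)
  if (is.null(range)) range <- detect_linear_range(tab, rel_tol)
  if (range[1] >= range[2])
    tz_domain_error("linear range must satisfy P_min < P_max")
  tab$in_range <- tab$power >= range[1] & tab$power <= range[2]
  sub <- tab[tab$in_range, ]
  if (nrow(sub) < 2)
    tz_insufficient_data("at least 2 stiffness points inside the linear range")
  weighted <- all(is.finite(sub$stderr)) && all(sub$stderr > 0)
  fit <- if (weighted)
    stats::lm(stiffness ~ power, data = sub, weights = 1 / sub$stderr^2)
  else
    stats::lm(stiffness ~ power, data = sub)
  co <- stats::coef(fit)
  exact <- nrow(sub) == 2
  sm <- suppressWarnings(summary(fit))
  ses <- if (exact) c(0, 0) else sm$coefficients[, "Std. Error"]
  r2 <- if (exact) 1 else sm$r.squared
  structure(list(slope = unname(co["power"]),
                 intercept = unname(co["(Intercept)"]),
                 slope_se = unname(ses[2]),
                 intercept_se = unname(ses[1]),
                 df = stats::df.residual(fit),
                 linear_range = c(P_min = unname(range[1]),
                                  P_max = unname(range[2])),
                 r_squared = r2,
                 weighted = weighted,
                 points = tab),
            class = "trap_model")
}

#' Evaluate trap stiffness at a laser power
#'
#' `stiffness_at(P) = slope * P + intercept`, valid only inside the linear
#' range of the trap; powers beyond the saturation knee were discarded in
#' calibration and evaluating there is an error, not an extrapolation.
#'
#' @param model A [fit_stiffness_vs_power()] result.
#' @param P Laser power (percent).
#' @return Trap stiffness (same units as the fitted points, N/m when
#'   sweeps are in SI).
#' @export
stiffness_at <- function(model, P) {
  stopifnot(inherits(model, "trap_model"))
  rng <- model$linear_range
  if (any(P < rng[1] | P > rng[2]))
    tz_range_error(sprintf(
      "power %s outside the trap's linear range [%g, %g]",
      paste(format(P[P < rng[1] | P > rng[2]]), collapse = ", "),
      rng[1], rng[2]))
  model$slope * P + model$intercept
}

#' @export
print.trap_model <- function(x, ...) {
  cat("Optical-trap stiffness model\n")
  cat(sprintf("  St(P) = %.6g * P + %.6g  (stiffness units per %% power)\n",
              x$slope, x$intercept))
  cat(sprintf("  linear range: %g%% - %g%%   R^2 = %.6f\n",
              x$linear_range[1], x$linear_range[2], x$r_squared))
  cat(sprintf("  %d stiffness points (%d in range)\n",
              nrow(x$points), sum(x$points$in_range)))
  invisible(x)
}
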