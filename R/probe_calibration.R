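#' One step of the colloidal-probe calibration protocol
#'
#' State of the probe at one laser power: the measured bead-centre
#' displacement from the zero-power reference, the trap-centre-to-bead-centre
#' offset at which the beam is parked, and the tilt between the optical
#' force and the cantilever surface normal.
#'
#' @param power Laser power (% of maximum).
#' @param displacement Bead-centre displacement dZ from the initial
#'   position (m), >= 0 once the trap is on.
#' @param trap_offset Trap-centre-to-bead-centre distance (m); the beam is
#'   parked at the distant edge of the bead, so the default working value is
#'   the bead radius.
#' @param tilt Angle between the applied force and the cantilever surface
#'   normal (rad), `[0, pi/2)`.
#' @return An object of class `deflection_step`.
#' @export
deflection_step <- function(power, displacement, trap_offset, tilt = 0) {
  assert_number(power, "power", lower = 0, upper = 100, strict_lower = TRUE)
  assert_number(displacement, "displacement")
  assert_number(trap_offset, "trap_offset", lower = 0)
  assert_number(tilt, "tilt", lower = 0, upper = pi / 2, strict_upper = TRUE)
  structure(list(power = power, displacement = displacement,
                 trap_offset = trap_offset, tilt = tilt),
            class = "deflection_step")
}

#' Optical force applied at one protocol step
#'
#' Force model for the beam parked off-centre at the bead edge:
#' `F = St(P) * trap_offset * cos(tilt)`, where `St(P)` is the calibrated
#' trap stiffness at the step's power. Treating the trap as a linear spring
#' out to the parking offset is an explicit modelling assumption (the
#' offset, of order the bead radius, is where the trap's restoring force is
#' applied); it is isolated here so alternative force models can be swapped
#' in.
#'
#' @param step A [deflection_step()].
#' @param trap A [fit_stiffness_vs_power()] trap model; the step's power
#'   must lie inside its linear range.
#' @return Force (N).
#' @export
step_force <- function(step, trap) {
  stopifnot(inherits(step, "deflection_step"))
  if (step$trap_offset == 0)
    warning("trap_offset = 0: the parked beam exerts no modelled force")
  St <- stiffness_at(trap, step$power)
  cosine_correction(St * step$trap_offset, step$tilt)
}

#' Spring constant of the probe at one step (Hooke's law)
#'
#' `k = F / dZ`: the optical force is balanced by the cantilever's elastic
#' restoring force at the observed deflection.
#'
#' @param step A [deflection_step()] with `displacement > 0`.
#' @param force Applied force (N).
#' @return An object of class `spring_point`: `power`, `force` (N), `k`
#'   (N/m).
#' @export
spring_constant <- function(step, force) {
  stopifnot(inherits(step, "deflection_step"))
  if (step$displacement <= 0)
    tz_domain_error("no deflection measured: displacement must be > 0")
  structure(list(power = step$power, force = force,
                 k = force / step$displacement),
            class = "spring_point")
}

spring_table <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("power", "k") %in% names(points)))
      tz_domain_error("spring-point table needs columns power, k")
    tab <- points
  } else {
    tab <- do.call(rbind, lapply(points, function(p)
      data.frame(power = p$power, force = p$force, k = p$k)))
  }
  if (any(tab$k <= 0))
    tz_domain_error("non-positive spring constant: mis-tracked frames?")
  tab[order(tab$power), , drop = FALSE]
}

#' Constant cantilever model
#'
#' For rectangular cantilevers the spring constant does not change over a
#' wide power range: the model is the mean of the per-step spring constants
#' with its sample standard deviation. At least 5 points are required (the
#' protocol repeats the measurement more than 5 times).
#'
#' @param points List of [spring_constant()] results or a data frame with
#'   columns `power`, `k`.
#' @return An object of class `cantilever_model` with `kind = "constant"`,
#'   `k_mean`, `k_sd`, `n`, `points`, `sse`.
#' @export
fit_constant_model <- function(points) {
  tab <- spring_table(points)
  if (nrow(tab) < 5)
    tz_insufficient_data("constant model needs >= 5 spring points")
  k_mean <- mean(tab$k)
  structure(list(kind = "constant",
                 k_mean = k_mean,
                 k_sd = stats::sd(tab$k),
                 n = nrow(tab),
                 points = tab,
                 sse = sum((tab$k - k_mean)^2),
                 n_params = 1L),
            class = "cantilever_model")
}

#' Logarithmic-plus-plateau cantilever model
#'
#' V-shape (triangular) cantilevers show a nonlinear spring constant: below
#' a breakpoint power `P*` it follows `k(P) = a ln(P) + b P + c`
#' (least-squares fit), above `P*` it is a plateau described by mean and
#' standard deviation. When `breakpoint` is not supplied it is chosen by
#' exhaustive search over the observed powers, minimizing the combined
#' residual sum of squares of the two branches (requiring >= 5 points at or
#' below and >= 2 above each candidate). With a supplied breakpoint and no
#' points above it, the plateau level is the log branch evaluated at `P*`
#' and `plateau_n` is 0.
#'
#' The printed piecewise functions of real V-shape probes need not be
#' continuous at `P*`; the discontinuity magnitude
#' `|a ln(P*) + b P* + c - k_mean|` is reported as `gap`, not enforced to
#' zero.
#'
#' @param points List of spring points or data frame (`power`, `k`).
#' @param breakpoint Optional breakpoint power `P*` (%).
#' @return A `cantilever_model` with `kind = "log_piecewise"`, coefficients
#'   `a`, `b`, `c`, `breakpoint`, plateau `k_mean`/`k_sd`, `gap`, `sse`.
#' @export
fit_log_piecewise <- function(points, breakpoint = NULL) {
  tab <- spring_table(points)
  if (any(tab$power <= 0))
    tz_domain_error("powers must be positive for the logarithmic branch")

  fit_at <- function(bp) {
    lo <- tab[tab$power <= bp, ]
    hi <- tab[tab$power > bp, ]
    if (nrow(lo) < 5) return(NULL)
    fit <- stats::lm(k ~ log(power) + power, data = lo)
    co <- stats::coef(fit)
    a <- unname(co["log(power)"]); b <- unname(co["power"])
    cc <- unname(co["(Intercept)"])
    if (anyNA(c(a, b, cc))) return(NULL)  # degenerate design (e.g. one power)
    sse_lo <- sum(stats::resid(fit)^2)
    ses <- if (nrow(lo) > 3)
      suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
    else c("(Intercept)" = 0, "log(power)" = 0, "power" = 0)
    if (nrow(hi) >= 2) {
      k_mean <- mean(hi$k); k_sd <- stats::sd(hi$k)
      sse_hi <- sum((hi$k - k_mean)^2)
      plateau_n <- nrow(hi)
    } else if (nrow(hi) == 0) {
      k_mean <- a * log(bp) + b * bp + cc
      k_sd <- NA_real_; sse_hi <- 0; plateau_n <- 0L
    } else return(NULL)
    list(a = a, b = b, c = cc,
         a_se = unname(ses["log(power)"]), b_se = unname(ses["power"]),
         c_se = unname(ses["(Intercept)"]),
         df = stats::df.residual(fit),
         breakpoint = bp, k_mean = k_mean,
         k_sd = k_sd, plateau_n = plateau_n, sse = sse_lo + sse_hi)
  }

  if (is.null(breakpoint)) {
    cands <- unique(tab$power)
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    # candidates with no plateau side only arise at the top power; exclude
    fits <- Filter(function(f) f$plateau_n >= 2, fits)
    if (length(fits) == 0)
      tz_insufficient_data(
        "no admissible breakpoint: need >= 5 points below and >= 2 above")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  } else {
    assert_number(breakpoint, "breakpoint", lower = 0, strict_lower = TRUE)
    best <- fit_at(breakpoint)
    if (is.null(best))
      tz_insufficient_data(
        "log branch needs >= 5 points at or below the breakpoint (and 0 or >= 2 above)")
  }
  if (best$k_mean <= 0)
    tz_domain_error("plateau spring constant must be positive")
  log_at_bp <- best$a * log(best$breakpoint) + best$b * best$breakpoint + best$c
  degenerate <- abs(best$a) < 1e-12 && abs(best$b) < 1e-12
  if (degenerate)
    warning("log branch is degenerate (flat); a constant model is likely adequate")
  structure(c(best,
              list(kind = "log_piecewise",
                   gap = abs(log_at_bp - best$k_mean),
                   degenerate = degenerate,
                   n = nrow(tab),
                   points = tab,
                   n_params = 4L)),
            class = "cantilever_model")
}

#' Evaluate a cantilever model at a laser power
#'
#' Constant model: `k_mean` at any power. Log-piecewise model: the
#' logarithmic branch for `P <= P*`, the plateau `k_mean` above. During a
#' force-spectroscopy experiment the spring constant appropriate to the
#' applied force is read off this function.
#'
#' @param model A `cantilever_model`.
#' @param P Laser power (%), > 0 (the logarithm is undefined otherwise).
#' @return Spring constant (N/m); vectorized over `P`.
#' @export
model_k_at <- function(model, P) {
  stopifnot(inherits(model, "cantilever_model"))
  if (any(!is.finite(P) | P <= 0))
    tz_domain_error("P must be positive: ln(P) undefined at or below 0")
  if (model$kind == "constant") return(rep(model$k_mean, length(P)))
  ifelse(P <= model$breakpoint,
         model$a * log(P) + model$b * P + model$c,
         model$k_mean)
}

#' Fit a cantilever model with geometry-driven selection
#'
#' Rectangular geometry selects the constant model, V-shape the
#' log-piecewise model; `"auto"` fits both and compares residual sums with
#' a 2-per-parameter penalty (AIC-style: `n log(SSE/n) + 2 p`), falling
#' back to the constant model when the piecewise fit is inadmissible.
#'
#' @param points Spring points (list or data frame).
#' @param geometry `"rectangular"`, `"v_shape"`, or `"auto"`.
#' @param breakpoint Optional breakpoint forwarded to
#'   [fit_log_piecewise()].
#' @return A `cantilever_model`.
#' @export
fit_cantilever <- function(points,
                           geometry = c("auto", "rectangular", "v_shape"),
                           breakpoint = NULL) {
  geometry <- match.arg(geometry)
  if (geometry == "rectangular") return(fit_constant_model(points))
  if (geometry == "v_shape") return(fit_log_piecewise(points, breakpoint))
  const <- fit_constant_model(points)
  piece <- tryCatch(fit_log_piecewise(points, breakpoint),
                    tz_error = function(e) NULL)
  if (is.null(piece)) return(const)
  tab <- spring_table(points)
  n <- nrow(tab)
  # Spring constants come from k = F / dZ with (near-)uniform jitter on the
  # measured deflection dZ, so k-space residuals are heteroscedastic (noisier
  # at low power). When the per-point force is known, compare the model
  # *kinds* on the homoscedastic displacement scale, each at its dz-space
  # optimum: for the constant kind that is the through-origin regression of
  # dZ on F (the reported model still uses the mean +/- sd convention).
  sse_of <- function(m) {
    if (!is.null(tab$force)) {
      dz <- tab$force / tab$k
      if (m$kind == "constant") {
        inv_k <- sum(tab$force * dz) / sum(tab$force^2)
        sum((dz - tab$force * inv_k)^2)
      } else sum((dz - tab$force / model_k_at(m, tab$power))^2)
    } else sum((tab$k - model_k_at(m, tab$power))^2)
  }
  # AICc: with ~9 protocol points and a 4-parameter alternative the
  # small-sample correction matters, plain AIC overfits
  crit <- function(m) {
    p <- m$n_params + 1  # + residual variance
    if (n - p - 1 < 1) return(Inf)
    n * log(max(sse_of(m), 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }
  if (crit(piece) < crit(const)) piece else const
}

#' @export
print.cantilever_model <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Cantilever model: constant  k = %.4f +/- %.4f N/m (n = %d)\n",
                x$k_mean, x$k_sd, x$n))
  } else {
    cat("Cantilever model: logarithmic + plateau\n")
    cat(sprintf("  P <= %g%%: k(P) = %.4f ln(P) %+.4f P %+.4f\n",
                x$breakpoint, x$a, x$b, x$c))
    cat(sprintf("  P  > %g%%: k = %.4f %s N/m (plateau, n = %d)\n",
                x$breakpoint, x$k_mean,
                if (is.na(x$k_sd)) "" else sprintf("+/- %.4f", x$k_sd),
                x$plateau_n))
    cat(sprintf("  discontinuity at breakpoint: %.4g N/m\n", x$gap))
  }
  invisible(x)
}

#' Run the full colloidal-probe calibration protocol
#'
#' Executes the image-based calibration on a series of frames: the first
#' frame is the zero-power reference (trap off), each subsequent frame is
#' taken at a strictly increasing laser power with the beam parked at the
#' bead edge. Per frame the bead centre is localized, its Z-displacement
#' from the reference converted to metres, the applied force computed from
#' the trap model, and Hooke's law gives a per-power spring constant; the
#' cantilever model selected by `geometry` is then fitted.
#'
#' @param frames List of [bead_image()]s (or file paths readable by
#'   [read_frame()]); `length(frames) == length(powers) + 1`, first frame =
#'   reference.
#' @param powers Strictly increasing laser powers (%) of the powered
#'   frames; at least 5.
#' @param trap Trap model ([fit_stiffness_vs_power()]); all powers must be
#'   inside its linear range.
#' @param config A [calibration_config()] providing `pixel_size`,
#'   `trap_offset`, `tilt`, `geometry` (overridden by `geometry` argument
#'   if given).
#' @param geometry Optional override of `config$geometry`.
#' @param strategy Localization strategy for [robust_center()].
#' @return List with elements `model` (a `cantilever_model`) and `steps`
#'   (per-step data frame: power, centre coordinates, displacement,
#'   force, k).
#' @export
run_protocol <- function(frames, powers, trap, config,
                         geometry = NULL, strategy = "lsq_circle") {
  stopifnot(inherits(trap, "trap_model"))
  if (length(powers) < 5)
    tz_insufficient_data("the protocol requires more than 5 repetitions: >= 5 powered frames")
  if (any(diff(powers) <= 0))
    tz_protocol_error("laser powers must be strictly increasing")
  if (length(frames) != length(powers) + 1)
    tz_protocol_error("need one zero-power reference frame plus one frame per power")
  frames <- lapply(frames, function(f)
    if (is.character(f)) read_frame(f, config$pixel_size) else f)
  geometry <- if (is.null(geometry)) config$geometry else geometry
  seed0 <- if (is.null(config$seed)) 1L else config$seed
  loc <- function(i) locate_bead(frames[[i]], strategy = strategy,
                                 seed = child_seed(seed0, i))
  ref <- loc(1)
  steps <- vector("list", length(powers))
  sp <- vector("list", length(powers))
  for (i in seq_along(powers)) {
    est <- loc(i + 1)
    d <- displacement(est, ref, config$pixel_size)
    dz <- unname(d["dz"])
    if (dz <= 0)
      tz_domain_error(sprintf(
        "frame %d: non-positive Z displacement (%.3g m); mis-tracked frame?",
        i + 1, dz))
    st <- deflection_step(powers[i], dz, config$trap_offset, config$tilt)
    f <- step_force(st, trap)
    sp[[i]] <- spring_constant(st, f)
    steps[[i]] <- data.frame(power = powers[i],
                             center_y_px = est$center_y,
                             center_z_px = est$center_z,
                             radius_px = est$radius,
                             dz_m = dz, force_n = f, k_n_per_m = sp[[i]]$k)
  }
  model <- fit_cantilever(sp, geometry)
  list(model = model, steps = do.call(rbind, steps), reference = ref)
}
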