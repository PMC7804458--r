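# Synthetic instrument data with known ground truth. The generator stands in
# for the three raw input kinds of the calibration workflow (drag sweeps,
# bright-field frames, protocol series) so every stage and the end-to-end
# protocol are testable without an instrument.

#' Ground truth for synthetic calibration data
#'
#' Fixes every parameter of the emulated experiment: the true trap
#' stiffness line and its saturation knee, the imaged bead, the cantilever
#' kind and its true spring-constant parameters, and the noise levels. All
#' stochastic generation derives from the mandatory `seed`.
#'
#' Defaults emulate the study conditions: a 15 um glass bead imaged at
#' 30 nm/px (500 px diameter), water viscosity, a trap line
#' `St(P) = 1.039 P + 0.2582` in mN/m with saturation above 60% power, the
#' beam parked one bead radius off-centre, and either a rectangular
#' cantilever of 0.030 N/m or a V-shape cantilever following
#' `k(P) = 0.0528 ln P - 0.0009 P - 0.0422` with a 0.1171 N/m plateau
#' above 30% power.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param trap_slope,trap_intercept True stiffness line (N/m per %, N/m).
#' @param knee Saturation knee (% power); the line holds below, stiffness
#'   is flat above.
#' @param bead_radius_px Imaged bead radius (px).
#' @param pixel_size Physical pixel size (m/px).
#' @param viscosity Medium dynamic viscosity (Pa s).
#' @param height Sphere-centre-to-wall distance (m); default three bead
#'   radii.
#' @param trap_offset Trap-to-bead-centre parking offset (m); default the
#'   bead radius ("parked at the distant edge").
#' @param tilt Force-to-normal tilt angle (rad).
#' @param cantilever `"rectangular"` or `"v_shape"`.
#' @param k0 True spring constant of the rectangular cantilever (N/m).
#' @param log_a,log_b,log_c True log-branch coefficients of the V-shape
#'   cantilever (`k = a ln P + b P + c`, N/m).
#' @param log_breakpoint Breakpoint `P*` (%) of the V-shape model.
#' @param plateau True plateau spring constant above `P*` (N/m).
#' @param image_noise_sd Additive Gaussian image noise, on normalized
#'   intensity.
#' @param displacement_noise_px Bead-position jitter (px).
#' @param sawtooth Trap-width sawtooth offset amplitude in the drag sweeps
#'   (m).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(seed,
                         trap_slope = 1.039e-3,
                         trap_intercept = 0.2582e-3,
                         knee = 60,
                         bead_radius_px = 250,
                         pixel_size = 30e-9,
                         viscosity = 1e-3,
                         height = NULL,
                         trap_offset = NULL,
                         tilt = 0,
                         cantilever = c("rectangular", "v_shape"),
                         k0 = 0.030,
                         log_a = 0.0528, log_b = -0.0009, log_c = -0.0422,
                         log_breakpoint = 30, plateau = 0.1171,
                         image_noise_sd = 0.02,
                         displacement_noise_px = 0.5,
                         sawtooth = 0.25e-6) {
  cantilever <- match.arg(cantilever)
  assert_number(seed, "seed")
  radius_m <- bead_radius_px * pixel_size
  if (is.null(height)) height <- 3 * radius_m
  if (is.null(trap_offset)) trap_offset <- radius_m
  tr <- structure(list(seed = as.integer(seed),
                       trap_slope = trap_slope,
                       trap_intercept = trap_intercept,
                       knee = knee,
                       bead_radius_px = bead_radius_px,
                       pixel_size = pixel_size,
                       bead_radius_m = radius_m,
                       viscosity = viscosity,
                       height = height,
                       trap_offset = trap_offset,
                       tilt = tilt,
                       cantilever = cantilever,
                       k0 = k0,
                       log_a = log_a, log_b = log_b, log_c = log_c,
                       log_breakpoint = log_breakpoint, plateau = plateau,
                       image_noise_sd = image_noise_sd,
                       displacement_noise_px = displacement_noise_px,
                       sawtooth = sawtooth),
                  class = "ground_truth")
  assert_number(tr$trap_slope, "trap_slope", lower = 0, strict_lower = TRUE)
  assert_number(tr$knee, "knee", lower = 0, upper = 100, strict_lower = TRUE)
  tr
}

#' True trap stiffness at a power (with saturation)
#'
#' The generating stiffness: linear below the knee, flat above.
#'
#' @param truth A [ground_truth()].
#' @param P Power (%); vectorized.
#' @return Stiffness (N/m).
#' @export
true_stiffness <- function(truth, P) {
  stopifnot(inherits(truth, "ground_truth"))
  truth$trap_slope * pmin(P, truth$knee) + truth$trap_intercept
}

#' True cantilever spring constant at a power
#'
#' @param truth A [ground_truth()].
#' @param P Power (%); vectorized, > 0.
#' @return k (N/m).
#' @export
true_spring_constant <- function(truth, P) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(P <= 0)) tz_domain_error("P must be positive")
  if (truth$cantilever == "rectangular") return(rep(truth$k0, length(P)))
  ifelse(P <= truth$log_breakpoint,
         truth$log_a * log(P) + truth$log_b * P + truth$log_c,
         truth$plateau)
}

#' Trap model carrying the generator's true stiffness line
#'
#' @param truth A [ground_truth()].
#' @param P_min Lower bound of the declared linear range (default 1%).
#' @return A `trap_model` usable with [stiffness_at()] and
#'   [run_protocol()].
#' @export
true_trap_model <- function(truth, P_min = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  structure(list(slope = truth$trap_slope,
                 intercept = truth$trap_intercept,
                 linear_range = c(P_min = P_min, P_max = truth$knee),
                 r_squared = 1,
                 points = data.frame(power = numeric(0),
                                     stiffness = numeric(0),
                                     stderr = numeric(0),
                                     in_range = logical(0))),
            class = "trap_model")
}

#' Render a synthetic bright-field bead image
#'
#' A dark disk on a bright background with a 1-px Gaussian edge profile and
#' additive Gaussian intensity noise, fully determined by the seed. The
#' analytic disk mask and the true sub-pixel centre are attached as
#' attribute `"truth"`.
#'
#' @param truth A [ground_truth()].
#' @param center True sub-pixel centre `c(y, z)` in 0-based px.
#' @param size Frame side length (px).
#' @param seed Seed for the image noise (default `truth$seed`).
#' @param edge_sd Edge blur (px).
#' @return A [bead_image()].
#' @export
make_bead_image <- function(truth, center, size, seed = truth$seed,
                            edge_sd = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  r <- truth$bead_radius_px
  margin <- 0.1 * r
  if (center[1] - r < margin || center[2] - r < margin ||
      center[1] + r > size - 1 - margin || center[2] + r > size - 1 - margin)
    tz_domain_error("bead does not fit in the frame with a 10%-radius margin")
  zc <- center[2]; yc <- center[1]
  dz2 <- (0:(size - 1) - zc)^2
  dy2 <- (0:(size - 1) - yc)^2
  d <- sqrt(outer(dz2, dy2, `+`))
  bright <- 0.85; dark <- 0.15
  img <- bright - (bright - dark) * stats::pnorm((r - d) / edge_sd)
  if (truth$image_noise_sd > 0)
    img <- img + with_seed(seed,
      matrix(stats::rnorm(size * size, sd = truth$image_noise_sd), size, size))
  out <- bead_image(img, truth$pixel_size)
  attr(out, "truth") <- list(center = c(y = yc, z = zc), radius_px = r,
                             mask = (d <= r) * 1L)
  out
}

#' Generate a synthetic drag-calibration sweep
#'
#' Emulates the sawtooth stage protocol at one laser power: per stage
#' speed, the bead displacement is the wall-corrected drag force divided by
#' the true trap stiffness, plus a trap-width offset whose sign alternates
#' with the stage direction, plus Gaussian localization noise.
#'
#' @param truth A [ground_truth()].
#' @param power Laser power (%).
#' @param speeds Signed stage speeds (m/s); the sawtooth protocol
#'   alternates their sign.
#' @param seed Seed for the displacement noise (default derived from
#'   `truth$seed` and `power`).
#' @return A [drag_sweep()].
#' @export
make_drag_sweep <- function(truth, power, speeds,
                            seed = child_seed(truth$seed, power)) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(speeds) < 4)
    tz_insufficient_data("at least 4 stage speeds per sweep")
  St <- true_stiffness(truth, power)
  cond <- drag_conditions(truth$viscosity, truth$bead_radius_m, truth$height)
  force <- vapply(speeds, function(v)
    drag_force(drag_conditions(cond$viscosity, cond$radius, cond$height, v)),
    numeric(1))
  disp <- force / St + sign(speeds) * truth$sawtooth
  noise_sd <- truth$displacement_noise_px * truth$pixel_size
  if (noise_sd > 0)
    disp <- disp + with_seed(seed, stats::rnorm(length(disp), sd = noise_sd))
  drag_sweep(power, data.frame(speed = speeds, displacement = disp), cond)
}

#' Generate a full synthetic calibration-protocol run
#'
#' Produces the zero-power reference frame plus one frame per laser power.
#' The true per-power displacement follows the protocol physics: the trap
#' force `St(P) * trap_offset * cos(tilt)` balanced by the cantilever at
#' `dZ = F / k(P)`; bead centres are jittered by the displacement noise and
#' frames rendered with [make_bead_image()]. Optionally writes frames
#' (TIFF), a manifest CSV and the ground truth (JSON) to a directory.
#'
#' @param truth A [ground_truth()]; all `powers` must be at or below the
#'   trap knee.
#' @param powers Strictly increasing powers (%), >= 5 of them.
#' @param out_dir Optional output directory.
#' @param size Frame side (px); computed to fit the largest displacement
#'   when `NULL`.
#' @return List: `frames` (list of `bead_image`, reference first), `powers`,
#'   `manifest` (data frame `frame`, `power_percent`), `trap` (true trap
#'   model), `table` (per-step truth: power, k, force, displacement), and
#'   `truth`.
#' @export
make_protocol_run <- function(truth, powers, out_dir = NULL, size = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(powers) < 5)
    tz_insufficient_data("the protocol requires >= 5 powered frames")
  if (any(diff(powers) <= 0))
    tz_protocol_error("powers must be strictly increasing")
  if (any(powers > truth$knee))
    tz_domain_error("protocol powers must stay inside the trap's linear range")
  St <- true_stiffness(truth, powers)
  force <- St * truth$trap_offset * cos(truth$tilt)
  k_true <- true_spring_constant(truth, powers)
  dz_m <- force / k_true
  dz_px <- dz_m / truth$pixel_size
  r <- truth$bead_radius_px
  pad <- ceiling(0.15 * r) + 8
  if (is.null(size))
    size <- ceiling(2 * r + max(dz_px) + 2 * pad + 6 * truth$displacement_noise_px)
  size <- max(size, 64)
  ref_center <- c(y = size / 2, z = r + pad)
  if (ref_center["z"] + max(dz_px) + r > size - 1 - 0.1 * r)
    tz_domain_error("largest displacement exceeds the frame margin")
  jitter <- function(i) {
    if (truth$displacement_noise_px == 0) return(c(0, 0))
    with_seed(child_seed(truth$seed, 5000 + i),
              stats::rnorm(2, sd = truth$displacement_noise_px))
  }
  centers <- vector("list", length(powers) + 1)
  centers[[1]] <- ref_center + jitter(1)
  for (i in seq_along(powers))
    centers[[i + 1]] <- c(ref_center["y"], ref_center["z"] + dz_px[i]) +
      jitter(i + 1)
  frames <- lapply(seq_along(centers), function(i)
    make_bead_image(truth, centers[[i]], size,
                    seed = child_seed(truth$seed, i)))
  manifest <- data.frame(
    frame = sprintf("frame_%02d.tif", seq_along(centers) - 1L),
    power_percent = c(0, powers))
  run <- list(frames = frames, powers = powers, manifest = manifest,
              trap = true_trap_model(truth, P_min = min(powers, 1)),
              table = data.frame(power = powers, k_true = k_true,
                                 force_n = force, dz_m = dz_m),
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(frames))
      write_frame(frames[[i]], file.path(out_dir, manifest$frame[i]))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    write_report(unclass(truth), file.path(out_dir, "truth.json"),
                 kind = "ground_truth")
  }
  run
}
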