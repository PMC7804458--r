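# Independent oracles used across the suite.

# Momentum-balance partial-ray tracer: sums the first reflected ray and the
# transmitted rays escaping after n = 0..N internal reflections. The reflected
# ray is deviated by -(pi - 2*theta) (away from the axis), each escaping ray
# by 2(theta - r) + n(pi - 2r) (towards it). Force = (n_medium/c) *
# (incident momentum flux - sum of outgoing fluxes), decomposed parallel /
# perpendicular to the incident direction. Entirely independent of the
# closed-form expressions in trap_forces().
oracle_ray_forces <- function(theta, media, P = 1, N = 60) {
  r <- snell_refraction(theta, media)
  fr <- fresnel_coefficients(theta, media)
  R <- fr$R
  Tt <- fr$T
  c0 <- 299792458
  d_refl <- -(pi - 2 * theta)
  n <- 0:N
  d_trans <- 2 * (theta - r) + n * (pi - 2 * r)
  par_comp <- 1 - R * cos(d_refl) - sum(Tt^2 * R^n * cos(d_trans))
  perp_comp <- -R * sin(d_refl) - sum(Tt^2 * R^n * sin(d_trans))
  scale <- media$n_medium * P / c0
  # perpendicular component corresponds to the printed F_Z, parallel to F_X
  list(F_Z = scale * perp_comp, F_X = scale * par_comp)
}

# Brute-force geometric circle fit: numerically minimize the sum of squared
# radial residuals over (center, radius), started from the centroid.
bruteforce_circle <- function(pts) {
  obj <- function(par) {
    d <- sqrt((pts$y - par[1])^2 + (pts$z - par[2])^2)
    sum((d - par[3])^2)
  }
  start <- c(mean(pts$y), mean(pts$z),
             mean(sqrt((pts$y - mean(pts$y))^2 + (pts$z - mean(pts$z))^2)))
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(center = fit$par[1:2], radius = fit$par[3])
}

# Points on a circle, optionally jittered radially.
circle_points <- function(n, center, radius, noise_sd = 0, seed = NULL) {
  gen <- function() {
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    rr <- radius + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    data.frame(y = center[1] + rr * cos(ang), z = center[2] + rr * sin(ang))
  }
  if (is.null(seed)) gen() else tweezercal:::with_seed(seed, gen())
}

# Sawtooth stage-speed schedule: alternating sign, growing magnitude.
sawtooth_speeds <- function(n_mag = 8, v_min = 0.05, v_max = 0.4) {
  rep(c(1, -1), n_mag) * rep(seq(v_min, v_max, length.out = n_mag), each = 2)
}

# Spring points generated directly from a ground truth at given powers,
# with bead-position jitter applied to the deflection (bypassing image
# rendering; the protocol physics is identical to make_protocol_run()).
synthetic_spring_points <- function(truth, powers, seed = truth$seed) {
  St <- true_stiffness(truth, powers)
  force <- St * truth$trap_offset * cos(truth$tilt)
  dz <- force / true_spring_constant(truth, powers)
  if (truth$displacement_noise_px > 0)
    dz <- dz + tweezercal:::with_seed(seed,
      stats::rnorm(length(dz),
                   sd = truth$displacement_noise_px * truth$pixel_size))
  data.frame(power = powers, force = force, k = force / dz)
}
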