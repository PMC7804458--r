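toy_trap <- function(slope = 2e-3, intercept = 0, range = c(1, 60)) {
  powers <- seq(range[1], range[2], length.out = 6)
  fit_stiffness_vs_power(
    data.frame(power = powers, stiffness = slope * powers + intercept),
    range = range)
}

test_that("step_force applies the parked-beam force model with tilt", {
  # stiffness_at(P) = 2 pN/um at P = 1, offset 15 um -> 30 pN
  trap <- toy_trap(slope = 2e-6, intercept = 0, range = c(1, 60))
  st <- deflection_step(1, 1e-6, trap_offset = 15e-6)
  expect_equal(step_force(st, trap), 30e-12, tolerance = 1e-12)
  tilted <- deflection_step(1, 1e-6, trap_offset = 15e-6, tilt = pi / 3)
  expect_equal(step_force(tilted, trap), 15e-12, tolerance = 1e-12)
  degen <- deflection_step(1, 1e-6, trap_offset = 0)
  expect_warning(f0 <- step_force(degen, trap), "no modelled force")
  expect_identical(f0, 0)
  outside <- deflection_step(80, 1e-6, trap_offset = 15e-6)
  expect_error(step_force(outside, trap), class = "tz_range_error")
})

test_that("spring_constant is Hooke's law with scale invariance", {
  st <- deflection_step(10, 300e-9, trap_offset = 7.5e-6)
  sp <- spring_constant(st, 30e-12)
  expect_equal(sp$k, 0.1e-3)
  st2 <- deflection_step(10, 600e-9, trap_offset = 7.5e-6)
  expect_equal(spring_constant(st2, 60e-12)$k, sp$k)
  bad <- deflection_step(10, 0, trap_offset = 7.5e-6)
  expect_error(spring_constant(bad, 30e-12), class = "tz_domain_error")
})

test_that("homogeneity: scaling stiffness and displacement leaves k unchanged", {
  trap1 <- toy_trap(slope = 2e-6)
  trap2 <- toy_trap(slope = 6e-6)
  s1 <- deflection_step(20, 1e-6, trap_offset = 7.5e-6)
  s2 <- deflection_step(20, 3e-6, trap_offset = 7.5e-6)
  k1 <- spring_constant(s1, step_force(s1, trap1))$k
  k2 <- spring_constant(s2, step_force(s2, trap2))$k
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("fit_constant_model: mean/sd bookkeeping and data requirements", {
  same <- data.frame(power = seq(5, 45, 10), k = rep(0.030, 5))
  m <- fit_constant_model(same)
  expect_equal(m$k_mean, 0.030)
  expect_identical(m$k_sd, 0)
  expect_error(fit_constant_model(same[1:4, ]),
               class = "tz_insufficient_data")
  expect_error(
    fit_constant_model(data.frame(power = seq(5, 45, 10),
                                  k = c(0.03, 0.03, -0.01, 0.03, 0.03))),
    class = "tz_domain_error")
  # recovery: k_mean close to generator truth on noisy points
  truth <- ground_truth(seed = 61)
  pts <- synthetic_spring_points(truth, seq(5, 30, 5))
  m <- fit_constant_model(pts)
  expect_lt(abs(m$k_mean - truth$k0), 3 * m$k_sd / sqrt(m$n) + 1e-12)
})

test_that("fit_log_piecewise recovers printed V-shape coefficients exactly", {
  P <- seq(5, 30, 5)
  k <- 0.0528 * log(P) - 0.0009 * P - 0.0422
  m <- fit_log_piecewise(data.frame(power = P, k = k), breakpoint = 30)
  expect_equal(m$a, 0.0528, tolerance = 1e-10)
  expect_equal(m$b, -0.0009, tolerance = 1e-10)
  expect_equal(m$c, -0.0422, tolerance = 1e-10)
  expect_identical(m$plateau_n, 0L)
  # with plateau points above the breakpoint, plateau = their mean +/- sd
  P2 <- c(P, 35, 40, 45)
  k2 <- c(k, 0.1171, 0.1180, 0.1162)
  m2 <- fit_log_piecewise(data.frame(power = P2, k = k2), breakpoint = 30)
  expect_equal(m2$k_mean, mean(c(0.1171, 0.1180, 0.1162)))
  expect_equal(m2$plateau_n, 3L)
  expect_gt(m2$gap, 0)  # printed functions are discontinuous at P*
})

test_that("fit_log_piecewise breakpoint search finds the generating knee", {
  truth <- ground_truth(seed = 71, cantilever = "v_shape")
  P <- c(seq(5, 30, 5), 35, 40, 45)
  pts <- synthetic_spring_points(truth, P)
  m <- fit_log_piecewise(pts)
  expect_equal(m$breakpoint, 30)
  expect_equal(m$a, truth$log_a, tolerance = 0.2)
  # plateau-only data: degenerate log branch is flagged
  flat <- data.frame(power = seq(5, 45, 5), k = rep(0.1171, 9))
  expect_warning(mf <- fit_log_piecewise(flat, breakpoint = 30), "degenerate")
  expect_true(mf$degenerate)
  # too few points below any candidate breakpoint
  expect_error(fit_log_piecewise(pts[1:4, ], breakpoint = 30),
               class = "tz_insufficient_data")
})

test_that("model_k_at evaluates both model kinds, at printed plateau values", {
  const <- fit_constant_model(data.frame(power = seq(5, 45, 10),
                                         k = rep(0.03, 5)))
  expect_equal(model_k_at(const, 7), 0.03)
  expect_equal(model_k_at(const, 99), 0.03)
  # k3: log branch below 30%, 0.1171 plateau above
  P <- seq(5, 30, 5)
  k3 <- data.frame(power = c(P, 35, 40, 45),
                   k = c(0.0528 * log(P) - 0.0009 * P - 0.0422,
                         rep(0.1171, 3)))
  m3 <- fit_log_piecewise(k3, breakpoint = 30)
  expect_equal(model_k_at(m3, 50), 0.1171, tolerance = 1e-12)
  expect_equal(model_k_at(m3, 20), 0.0528 * log(20) - 0.0009 * 20 - 0.0422,
               tolerance = 1e-10)
  # k4: 0.0750 plateau above 45%
  P4 <- seq(5, 45, 5)
  k4 <- data.frame(power = c(P4, 50, 55, 60),
                   k = c(0.0289 * log(P4) - 0.0003 * P4 - 0.0221,
                         rep(0.0750, 3)))
  m4 <- fit_log_piecewise(k4, breakpoint = 45)
  expect_equal(model_k_at(m4, 60), 0.0750, tolerance = 1e-12)
  expect_error(model_k_at(m3, 0), class = "tz_domain_error")
  expect_error(model_k_at(m3, -5), class = "tz_domain_error")
})

test_that("model_k_at reports the breakpoint discontinuity it carries", {
  P <- seq(5, 30, 5)
  k3 <- data.frame(power = c(P, 35, 40, 45),
                   k = c(0.0528 * log(P) - 0.0009 * P - 0.0422,
                         rep(0.1171, 3)))
  m <- fit_log_piecewise(k3, breakpoint = 30)
  jump <- abs(model_k_at(m, 30 + 1e-9) - model_k_at(m, 30))
  expect_equal(jump, m$gap, tolerance = 1e-6)
})

test_that("fit_cantilever auto-selects by penalized residuals", {
  # across seeds, auto must pick the generating kind in the large majority
  # of runs for both cantilever geometries
  powers <- c(seq(5, 30, 5), 35, 40, 45)
  hits_r <- sum(vapply(1:20, function(s) {
    pts <- synthetic_spring_points(
      ground_truth(seed = 300 + s, cantilever = "rectangular"), powers)
    fit_cantilever(pts, "auto")$kind == "constant"
  }, logical(1)))
  hits_v <- sum(vapply(1:20, function(s) {
    pts <- synthetic_spring_points(
      ground_truth(seed = 400 + s, cantilever = "v_shape"), powers)
    fit_cantilever(pts, "auto")$kind == "log_piecewise"
  }, logical(1)))
  expect_gte(hits_r, 16)
  expect_gte(hits_v, 18)
  # geometry hint overrides whatever auto would choose
  pts_v <- synthetic_spring_points(
    ground_truth(seed = 401, cantilever = "v_shape"), powers)
  expect_equal(fit_cantilever(pts_v, "rectangular")$kind, "constant")
})

test_that("run_protocol recovers a rectangular cantilever end to end", {
  truth <- ground_truth(seed = 91, bead_radius_px = 60,
                        cantilever = "rectangular")
  run <- make_protocol_run(truth, seq(5, 30, 5))
  cfg <- calibration_config(bead_radius = truth$bead_radius_m,
                            pixel_size = truth$pixel_size,
                            trap_offset = truth$trap_offset,
                            geometry = "rectangular", seed = 91)
  res <- run_protocol(run$frames, run$powers, run$trap, cfg)
  expect_equal(res$model$kind, "constant")
  expect_lt(abs(res$model$k_mean - truth$k0) / truth$k0, 0.05)
  expect_equal(nrow(res$steps), 6)
})

test_that("run_protocol enforces the calibration protocol", {
  truth <- ground_truth(seed = 92, bead_radius_px = 60)
  run <- make_protocol_run(truth, seq(5, 30, 5))
  cfg <- calibration_config(bead_radius = truth$bead_radius_m,
                            trap_offset = truth$trap_offset, seed = 92)
  expect_error(
    run_protocol(run$frames, rev(run$powers), run$trap, cfg),
    class = "tz_protocol_error")
  expect_error(
    run_protocol(run$frames[1:5], run$powers[1:4], run$trap, cfg),
    class = "tz_insufficient_data")
  expect_error(
    run_protocol(run$frames[1:6], run$powers, run$trap, cfg),
    class = "tz_protocol_error")
})
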