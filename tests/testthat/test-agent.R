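test_that("predict_relative applies the eye extrinsic transform", {
  # zero angles, zero offset: identity
  expect_vec_equal(predict_relative(c(2, 0.3), c(0, 0), L = 0, eye = 0),
                   c(2, 0.3, 1))
  # Eq-style substitution oracle with l = +0.5 (eye index 1)
  expect_vec_equal(predict_relative(c(2, 0.3), c(0, 0), L = 0.5, eye = 1),
                   c(2, -0.2, 1))
  expect_vec_equal(predict_relative(c(2, 0.3), c(0, 0), L = 0.5, eye = 0),
                   c(2, 0.8, 1))
  # left/right symmetry: mirroring y swaps the eyes' outputs (y-negated)
  set.seed(21)
  for (i in 1:10) {
    mu_a <- c(stats::runif(1, 1, 6), stats::runif(1, -2, 2))
    th <- stats::runif(2, -0.3, 0.3)
    a <- predict_relative(mu_a, th, 0.5, 0)
    b <- predict_relative(c(mu_a[1], -mu_a[2]), c(-th[1], th[2]), 0.5, 1)
    expect_vec_equal(b, c(a[1], -a[2], a[3]), tol = 1e-10)
  }
})

test_that("predict_projection matches the pinhole form", {
  expect_vec_equal(predict_projection(c(3, 0, 1), 1), c(1, 0))
  expect_vec_equal(predict_projection(c(2, 1, 1), 1), c(1, 0.5))
  expect_vec_equal(predict_projection(c(2, -1, 1), 1), c(1, -0.5))
  expect_error(predict_projection(c(0, 1, 1), 1), "zero depth")
})

test_that("attractor_fc pulls toward the camera-plane centre linearly", {
  expect_vec_equal(attractor_fc(c(1, 0), 1), c(0, 0))
  v <- attractor_fc(c(1, 0.4), 1)
  expect_equal(sqrt(sum(v^2)), 0.4)
  expect_lt(v[2] * 0.4, 0)  # directed toward the centre
  expect_vec_equal(attractor_fc(c(1, 0.4), 2), 2 * attractor_fc(c(1, 0.4), 1))
})

test_that("schedule_phase alternates in fixed blocks", {
  sch <- phase_schedule(100, "perception")
  expect_equal(schedule_phase(0, sch), "perception")
  expect_equal(schedule_phase(99, sch), "perception")
  expect_equal(schedule_phase(100, sch), "action")
  expect_equal(schedule_phase(199, sch), "action")
  expect_equal(schedule_phase(200, sch), "perception")
  phases <- vapply(0:999, schedule_phase, character(1), sched = sch)
  expect_equal(sum(phases == "perception"), 500)
  expect_equal(sum(phases == "action"), 500)
  expect_equal(rle(phases)$lengths, rep(100L, 10))
  sch2 <- phase_schedule(50, "action")
  expect_equal(schedule_phase(0, sch2), "action")
  expect_equal(schedule_phase(50, sch2), "perception")
})

test_that("an agent at the true state is a fixed point under noiseless input", {
  cfg <- test_cfg()
  target <- c(3, 0.7)
  ang <- depthsim:::fixation_angles(target, cfg$L)
  w <- world_state(target, ang, cfg$L, cfg$f)
  obs <- observe(w, fovea_noise("uniform"), cfg$far_clip)
  ag <- depth_agent(cfg, target, ang)
  for (t in 1:20) {
    ag2 <- step_agent(ag, obs, "perception")
    expect_lt(max(abs(ag2$mu_a - ag$mu_a)), 1e-6)
    expect_lt(max(abs(ag2$mu_theta - ag$mu_theta)), 1e-6)
    expect_lt(max(abs(ag2$mu_c - ag$mu_c)), 1e-6)
    ag <- ag2
  }
  expect_equal(ag$fe, 0)
})

test_that("the absolute belief is frozen during action phases", {
  cfg <- test_cfg()
  w <- world_state(c(4, 1), c(0.1, -0.1), cfg$L, cfg$f)
  ag <- depth_agent(cfg, c(3, 0), c(0.1, -0.1))
  obs <- observe(w, fovea_noise("uniform"), cfg$far_clip)
  mu_a0 <- ag$mu_a
  for (t in 1:50) ag <- step_agent(ag, obs, "action")
  expect_identical(ag$mu_a, mu_a0)
  expect_false(isTRUE(all.equal(ag$mu_theta, c(0.1, -0.1))))  # theta moved
  # but in the simultaneous (non-cycled) mode mu_a does move
  ag2 <- depth_agent(cfg, c(3, 0), c(0.1, -0.1))
  for (t in 1:50) ag2 <- step_agent(ag2, obs, "simultaneous")
  expect_false(isTRUE(all.equal(ag2$mu_a, mu_a0)))
})

test_that("perception-only inference reaches the triangulation oracle", {
  cfg <- test_cfg()
  set.seed(31)
  for (i in 1:3) {
    target <- c(stats::runif(1, 2, 6), stats::runif(1, -2, 2))
    mu0 <- c(stats::runif(1, 2, 6), 0)
    ag <- infer_parallel_noiseless(target, mu0, cfg)
    w <- world_state(target, c(0, 0), cfg$L, cfg$f)
    obs <- observe(w, fovea_noise("uniform"), cfg$far_clip)
    oracle <- triangulate_parallel(obs$sv[1], obs$sv[2], cfg$f, cfg$L)
    expect_equal(ag$mu_a, oracle, tolerance = 1e-2)
    expect_equal(oracle, target, tolerance = 1e-9)
  }
})

test_that("mirrored targets produce mirrored belief trajectories", {
  cfg <- test_cfg()
  tgt <- c(3.5, 1.3)
  a1 <- infer_parallel_noiseless(tgt, c(2.5, 0), cfg, nsteps = 600)
  a2 <- infer_parallel_noiseless(c(tgt[1], -tgt[2]), c(2.5, 0), cfg,
                                 nsteps = 600)
  expect_equal(a1$mu_a[1], a2$mu_a[1], tolerance = 1e-9)
  expect_equal(a1$mu_a[2], -a2$mu_a[2], tolerance = 1e-9)
})

test_that("divergence is detected and flagged", {
  cfg <- test_cfg(diverge_limit = 1)
  w <- world_state(c(4, 1), c(0, 0), cfg$L, cfg$f)
  ag <- depth_agent(cfg, c(2, 0), c(0, 0), action_enabled = FALSE)
  obs <- observe(w, fovea_noise("uniform"), cfg$far_clip)
  ag <- step_agent(ag, obs, "perception")
  expect_true(ag$diverged)
})
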