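# Shared helpers for the test suite. All fixtures are built in code.

# fast config for unit tests that do not need the full trial horizon
test_cfg <- function(...) depthsim_config(...)

# central-difference derivative of a scalar- or vector-valued function
num_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(length(fn(x))))
}

# run a perception-only, noiseless, parallel-eyes inference and return mu_a
infer_parallel_noiseless <- function(target, mu0, cfg = test_cfg(),
                                     nsteps = 2500) {
  w <- world_state(target, c(0, 0), cfg$L, cfg$f)
  ag <- depth_agent(cfg, mu0, c(0, 0), action_enabled = FALSE)
  obs <- observe(w, fovea_noise("uniform"), cfg$far_clip)
  for (t in seq_len(nsteps)) ag <- step_agent(ag, obs, "perception")
  ag
}

expect_vec_equal <- function(actual, expected, tol = 1e-10) {
  expect_equal(as.numeric(actual), as.numeric(expected), tolerance = tol)
}
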