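# Shipped defaults for the simulator. Geometry and noise parameters define
# the simulated world; precisions and learning gains are free model
# parameters, tuned once so that the inference converges within a trial,
# and recorded here.

#' Default simulator configuration
#'
#' Returns the full configuration list used by the agent, the generative
#' process and the trial runner. Any entry can be overridden via `...`.
#'
#' Geometry: eyes at `(0, -L)` (eye 0) and `(0, +L)` (eye 1), focal length
#' `f`, targets sampled with depth `x` in `depth_range` and lateral `y` in
#' `lateral_range`. Absolute eye angles derive from the vergence-
#' accommodation pair as `theta(0) = theta_a - theta_v`,
#' `theta(1) = theta_a + theta_v`.
#'
#' Fovea noise: visual noise standard deviation `exp(d / k)` where `d` is the
#' distance between the fixation point and the target (`k = 1.5`); zero in
#' uniform mode. When gaze rays do not intersect in front of the eyes the
#' fixation point is clipped to `far_clip` world units along the mean gaze
#' direction.
#'
#' Integration: explicit Euler with step `dt`; every "time step" of a phase
#' is one integrator step, and a phase lasts `cycle_length` steps. Learning
#' gains scale the effective step of each belief/error pathway.
#'
#' @param ... Named overrides of any default entry.
#' @return Named list of configuration values.
#' @export
depthsim_config <- function(...) {
  cfg <- list(
    # world geometry
    L = 0.5,                    # inter-eye half distance
    f = 50,                     # focal length (pixel-like image-plane units)
    depth_range = c(2, 6),      # target depth sampling range
    lateral_range = c(-2, 2),   # target lateral sampling range
    angle_limit = pi / 2,       # true eye angles clipped to (-limit, limit)
    far_clip = 8,               # fixation distance for non-intersecting gaze
    # fovea noise (generative process)
    k = 1.5,                    # noise scaling factor
    sigma_as_variance = FALSE,  # interpret exp(d/k) as variance instead of sd
    # integrator
    dt = 0.01,
    k_a = 1170,                 # learning gain, absolute-position belief
    k_theta = 0.067,            # learning gain, eye-angle belief
    k_c = 22,                   # learning gain, projected-point beliefs
    k_r = 420,                  # learning gain, relative-point beliefs
    k_err = 8.8,                # learning gain, relative-point error units
    k_err_c = 0.018,            # learning gain, projection error units
    k_err_v = 6.2,              # learning gain, visual error units
    k_err_p = 15000,            # learning gain, proprioceptive error unit
    k_act = 12,                 # action gain
    act_leak = 0.5,             # per-step leak of the motor signal
    # precisions (tuned jointly with the gains so the linearized message-
    # passing dynamics are stable and fast across the whole target box;
    # see the methods vignette)
    pi_v = 0.78, pi_c = 0.0087, pi_r = 1, pi_p = 300,
    gamma_a = 1, gamma_theta = 1, gamma_c = 1,
    # numerical safeguards around the projective singularity
    jac_floor = 1,              # min |depth| used in projection Jacobians
    min_rel_depth = 0.2,        # clamp on relative-point depth beliefs
    max_step = 0.05,            # trust-region cap per belief increment
    # fixation attractor
    lambda = 4,
    # action-perception schedule
    cycle_length = 100,
    n_cycles = 10,
    start_phase = "perception",
    mechanism = "zero_attractor_gain",  # or "zero_proprio_precision"
    # trial runner
    threshold = 0.1,            # success: final error below this (world units)
    angle_init_range = 0.3,     # active-vision initial angles ~ U(-r, r)
    diverge_limit = 1e8,        # abort when any belief exceeds this magnitude
    instantaneous_errors = FALSE
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

# signed eye offsets: eye 0 below the origin, eye 1 above
eye_offsets <- function(L) c(-L, L)

# absolute eye angles from the vergence-accommodation pair
eye_angles_abs <- function(theta_a, theta_v) {
  c(theta_a - theta_v, theta_a + theta_v)
}
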