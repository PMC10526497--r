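# The depth-estimation hierarchy. Two pathways (one per eye) descend from an
# absolute-position belief mu_a and a vergence-accommodation belief mu_theta:
# each predicts the target relative to one eye (mu_r), then its projection on
# that eye's camera plane (mu_c), which is compared with the visual
# observation. Prediction errors at every junction are dynamic units; their
# gradients climb back through the transforms, updating all beliefs at once.
# A fixation attractor on the projected beliefs, gated by the
# action-perception scheduler, produces vergence movements.

#' Create a depth-estimation agent
#'
#' Lower-level beliefs (`mu_r`, `mu_c`) are initialized self-consistently by
#' running the generative model forward from `mu_a0` and `mu_theta0`, so an
#' agent created at the true state with noiseless input sits at a fixed
#' point. All error units start at zero.
#'
#' @param cfg Configuration from [depthsim_config()].
#' @param mu_a0 Initial absolute-position belief `(x, y)`.
#' @param mu_theta0 Initial eye-angle belief `(theta_a, theta_v)`.
#' @param action_enabled Logical; `FALSE` for the parallel-gaze variant.
#' @return Agent state list.
#' @export
depth_agent <- function(cfg, mu_a0, mu_theta0 = c(0, 0), action_enabled = TRUE) {
  mu_r <- matrix(0, 2L, 2L)
  mu_c <- numeric(2L)
  for (i in 0:1) {
    r <- predict_relative(mu_a0, mu_theta0, cfg$L, i)
    mu_r[i + 1L, ] <- r[1:2]
    mu_c[i + 1L] <- predict_projection(r, cfg$f)[2]
  }
  list(
    cfg = cfg,
    mu_a = as.numeric(mu_a0), mu_a_p = c(0, 0),
    mu_theta = as.numeric(mu_theta0), mu_theta_p = c(0, 0),
    mu_r = mu_r,
    mu_c = mu_c, mu_c_p = numeric(2L),
    e_r = matrix(0, 2L, 3L),
    e_c = numeric(2L), e_v = numeric(2L), e_mu_c = numeric(2L),
    e_p = c(0, 0), e_mu_a = c(0, 0), e_mu_theta = c(0, 0),
    a = c(0, 0), action_enabled = isTRUE(action_enabled),
    fe = 0, diverged = FALSE
  )
}

#' Predict a target's position relative to one eye
#'
#' Applies the eye's extrinsic transform to the absolute belief:
#' `T(theta_i, l_i) %*% mu_a`, with the absolute angle `theta_i` derived from
#' the vergence-accommodation pair and `l_0 = -L`, `l_1 = +L`.
#'
#' @param mu_a Absolute position, length 2 `(x, y)` or homogeneous length 3.
#' @param mu_theta Eye-angle pair `(theta_a, theta_v)`.
#' @param L Inter-eye half distance.
#' @param eye Eye index, 0 or 1.
#' @return Homogeneous 3-vector in the eye's frame.
#' @export
predict_relative <- function(mu_a, mu_theta, L, eye) {
  stopifnot(eye %in% c(0, 1))
  if (length(mu_a) == 2) mu_a <- c(mu_a, 1)
  th <- eye_angles_abs(mu_theta[1], mu_theta[2])[eye + 1L]
  l <- eye_offsets(L)[eye + 1L]
  apply_transform(make_eye_transform(th, l), mu_a)
}

#' Predict the camera-plane projection of a relative belief
#'
#' @param mu_r Homogeneous 3-vector (or `(x, y)` pair) in an eye's frame,
#'   with nonzero depth.
#' @param f Focal length.
#' @return Homogeneous image point `(1, c)`.
#' @export
predict_projection <- function(mu_r, f) {
  if (length(mu_r) == 2) mu_r <- c(mu_r, 1)
  project_to_camera(mu_r, f)
}

#' Fixation attractor velocity
#'
#' The intended dynamics of a projected-point belief during fixation: a
#' velocity proportional to the displacement of `mu_c` from the centre of the
#' camera plane `(1, 0)`, directed toward the centre, scaled by the gain
#' `lambda`.
#'
#' @param mu_c Homogeneous image point `(1, c)` or scalar coordinate `c`.
#' @param lambda Nonnegative attractor gain.
#' @return Numeric 2-vector velocity on `(1, c)`; zero at the centre.
#' @export
attractor_fc <- function(mu_c, lambda) {
  cc <- if (length(mu_c) == 2) mu_c[2] else mu_c
  c(0, -lambda * cc)
}

#' Phase schedule of the action-perception cycle
#'
#' @param cycle_length Steps per phase (default 100).
#' @param start_phase Phase of the first block, `"perception"` or `"action"`.
#' @param mechanism How action is blocked during perception:
#'   `"zero_attractor_gain"` (default) or `"zero_proprio_precision"`.
#' @return List schedule.
#' @export
phase_schedule <- function(cycle_length = 100,
                           start_phase = c("perception", "action"),
                           mechanism = c("zero_attractor_gain",
                                         "zero_proprio_precision")) {
  list(cycle_length = as.integer(cycle_length),
       start_phase = match.arg(start_phase),
       mechanism = match.arg(mechanism))
}

#' Phase active at a given integrator step
#'
#' Strict alternation: the starting phase occupies blocks with even
#' `floor(t / cycle_length)`, the other phase the odd blocks.
#'
#' @param t Step index (0-based).
#' @param sched Schedule from [phase_schedule()].
#' @return `"perception"` or `"action"`.
#' @export
schedule_phase <- function(t, sched) {
  stopifnot(t >= 0)
  other <- if (sched$start_phase == "perception") "action" else "perception"
  if (t %/% sched$cycle_length %% 2 == 0) sched$start_phase else other
}

#' One integration step of the full agent
#'
#' Synchronously updates every belief and error unit from the current state
#' and observation. During an `"action"` phase the absolute belief is frozen
#' and the fixation attractor and motor update are active; during a
#' `"perception"` phase the attractor gain (or the proprioceptive precision,
#' depending on the configured mechanism) is zeroed and the action signal is
#' not updated; `"simultaneous"` runs everything at once (the non-cycled
#' control variant).
#'
#' @param agent Agent from [depth_agent()].
#' @param obs Observation from [observe()] (`sp`, `sv`).
#' @param phase `"perception"`, `"action"`, or `"simultaneous"`.
#' @return Updated agent; `agent$diverged` is set when any state leaves the
#'   finite range, and `agent$fe` holds the free-energy proxy of the step.
#' @export
step_agent <- function(agent, obs, phase = "perception") {
  cfg <- agent$cfg
  dt <- cfg$dt
  action_on <- agent$action_enabled && phase != "perception"
  lambda_eff <- cfg$lambda
  pi_p_eff <- cfg$pi_p
  if (phase == "perception") {
    if (cfg$mechanism == "zero_attractor_gain") lambda_eff <- 0
    else pi_p_eff <- 0
  }

  l <- eye_offsets(cfg$L)
  th <- eye_angles_abs(agent$mu_theta[1], agent$mu_theta[2])
  mu_a_h <- c(agent$mu_a, 1)

  # forward predictions and raw errors
  Tm <- list(make_eye_transform(th[1], l[1]), make_eye_transform(th[2], l[2]))
  raw_r <- matrix(0, 2L, 3L)
  raw_c <- numeric(2L); raw_v <- numeric(2L); raw_mu_c <- numeric(2L)
  pred_c <- numeric(2L)
  for (i in 1:2) {
    raw_r[i, ] <- c(agent$mu_r[i, ], 1) - apply_transform(Tm[[i]], mu_a_h)
    pred_c[i] <- cfg$f * agent$mu_r[i, 2] / agent$mu_r[i, 1]
    raw_c[i] <- agent$mu_c[i] - pred_c[i]
    raw_v[i] <- obs$sv[i] - agent$mu_c[i]
    raw_mu_c[i] <- agent$mu_c_p[i] - (-lambda_eff * agent$mu_c[i])
  }
  raw_p <- obs$sp - agent$mu_theta
  raw_mu_a <- agent$mu_a_p
  raw_mu_theta <- agent$mu_theta_p

  # free-energy proxy (monitoring only)
  agent$fe <- 0.5 * (cfg$pi_r * sum(raw_r^2) + cfg$pi_c * sum(raw_c^2) +
                     cfg$pi_v * sum(raw_v^2) + pi_p_eff * sum(raw_p^2) +
                     cfg$gamma_a * sum(raw_mu_a^2) +
                     cfg$gamma_theta * sum(raw_mu_theta^2) +
                     cfg$gamma_c * sum(raw_mu_c^2))

  # error-unit relaxation (always integrates, even for frozen beliefs)
  de <- cfg$k_err * dt
  if (isTRUE(cfg$instantaneous_errors)) {
    e_r <- raw_r * cfg$pi_r
    e_c <- raw_c * cfg$pi_c
    e_v <- raw_v * cfg$pi_v
    e_p <- raw_p * pi_p_eff
    e_mu_a <- raw_mu_a * cfg$gamma_a
    e_mu_theta <- raw_mu_theta * cfg$gamma_theta
    e_mu_c <- raw_mu_c * cfg$gamma_c
  } else {
    e_r <- agent$e_r + de * (raw_r - agent$e_r / cfg$pi_r)
    e_c <- agent$e_c + cfg$k_err_c * dt * (raw_c - agent$e_c / cfg$pi_c)
    e_v <- agent$e_v + cfg$k_err_v * dt * (raw_v - agent$e_v / cfg$pi_v)
    dep <- cfg$k_err_p * dt  # the proprioceptive reflex channel is fast
    e_p <- if (pi_p_eff > 0) agent$e_p + dep * (raw_p - agent$e_p / pi_p_eff)
           else agent$e_p * (1 - dep / cfg$pi_p)
    e_mu_a <- agent$e_mu_a + de * (raw_mu_a - agent$e_mu_a / cfg$gamma_a)
    e_mu_theta <- agent$e_mu_theta +
      de * (raw_mu_theta - agent$e_mu_theta / cfg$gamma_theta)
    e_mu_c <- agent$e_mu_c + de * (raw_mu_c - agent$e_mu_c / cfg$gamma_c)
  }

  # commit the error-unit updates before the belief updates, so beliefs
  # descend the gradient defined by the current-step error values
  agent$e_r <- e_r; agent$e_c <- e_c; agent$e_v <- e_v
  agent$e_p <- e_p
  agent$e_mu_a <- e_mu_a; agent$e_mu_theta <- e_mu_theta; agent$e_mu_c <- e_mu_c

  # gradients of the relative-point errors onto the parent beliefs
  grad_a <- c(0, 0)
  g_theta <- numeric(2L)  # per absolute eye angle
  for (i in 1:2) {
    bp <- backprop_point(Tm[[i]], agent$e_r[i, ])
    grad_a <- grad_a + bp[1:2]
    g_theta[i] <- backprop_param(deye_dtheta(th[i], l[i]), agent$e_r[i, ], mu_a_h)
  }

  # trust-region cap on per-step belief increments: transients far from
  # equilibrium are rate-limited; near equilibrium increments are far below
  # the cap, so fixed points and local dynamics are untouched
  cap <- function(v, m) pmin(pmax(v, -m), m)
  mstep <- cfg$max_step

  # belief updates (synchronous across beliefs, using the fresh errors)
  frozen_a <- phase != "perception" && agent$action_enabled
  if (phase == "simultaneous") frozen_a <- FALSE
  if (!frozen_a) {
    da <- cfg$k_a * dt
    agent$mu_a <- agent$mu_a + cap(da * (agent$mu_a_p + grad_a), mstep)
    agent$mu_a_p <- agent$mu_a_p + cap(da * (-agent$e_mu_a), mstep)
  }
  # chain rule theta(0) = theta_a - theta_v, theta(1) = theta_a + theta_v
  grad_theta <- c(g_theta[1] + g_theta[2], g_theta[2] - g_theta[1])
  dth <- cfg$k_theta * dt
  agent$mu_theta <- agent$mu_theta +
    cap(dth * (agent$mu_theta_p + grad_theta + agent$e_p), mstep)
  agent$mu_theta_p <- agent$mu_theta_p + cap(dth * (-agent$e_mu_theta), mstep)

  for (i in 1:2) {
    # projection Jacobian with a floored depth: |r_x| never enters the
    # denominators below jac_floor, which bounds the gradient magnitude near
    # the projective singularity without moving any fixed point with
    # admissible geometry (true relative depths exceed the floor)
    rx <- max(abs(agent$mu_r[i, 1]), cfg$jac_floor) * sign(agent$mu_r[i, 1])
    asc <- backprop_projection(c(rx, agent$mu_r[i, 2], 1), cfg$f, agent$e_c[i])
    agent$mu_r[i, ] <- agent$mu_r[i, ] +
      cap(cfg$k_r * dt * (-agent$e_r[i, 1:2] + asc), mstep)
    # keep the relative depth away from the camera plane
    if (agent$mu_r[i, 1] < cfg$min_rel_depth) agent$mu_r[i, 1] <- cfg$min_rel_depth
  }
  dc <- cfg$k_c * dt
  mstep_c <- mstep * cfg$f  # image-plane quantities live on the pixel scale
  agent$mu_c <- agent$mu_c + cap(dc *
    (agent$mu_c_p - agent$e_c + agent$e_v - lambda_eff * agent$e_mu_c), mstep_c)
  agent$mu_c_p <- agent$mu_c_p + cap(dc * (-agent$e_mu_c), mstep_c)

  # motor update: suppress the proprioceptive prediction error. The reflex
  # arc is the fastest loop in the system, so it reads the instantaneous
  # raw error rather than the (slow) dynamic unit, and the motor signal
  # leaks, which yields a well-damped quasi-proportional servo of the true
  # angles onto the angle belief.
  if (action_on && (phase != "perception")) {
    agent$a <- (1 - cfg$act_leak) * agent$a - cfg$k_act * dt * (pi_p_eff * raw_p)
  }

  m <- max(abs(c(agent$mu_a, agent$mu_theta, agent$mu_r, agent$mu_c)))
  if (!is.finite(m) || m > cfg$diverge_limit) agent$diverged <- TRUE
  agent
}
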