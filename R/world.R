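# The generative process: true target, true eye angles driven by action,
# noiseless proprioceptive readout and visual observations corrupted by
# fovea noise that grows exponentially with the distance between the point
# of fixation and the target.

#' Create the true world state
#'
#' @param target Numeric 2-vector `(x, y)`; depth `x` must be positive.
#' @param eye_angles Numeric 2-vector, true `(theta_a, theta_v)` in radians.
#' @param L Inter-eye half distance; eyes sit at `(0, -L)` and `(0, +L)`.
#' @param f Focal length.
#' @return List world state.
#' @export
world_state <- function(target, eye_angles = c(0, 0), L = 0.5, f = 1) {
  stopifnot(length(target) == 2, target[1] > 0, length(eye_angles) == 2)
  list(target = as.numeric(target), eye_angles = as.numeric(eye_angles),
       L = L, f = f)
}

#' Fovea noise model
#'
#' In nonuniform mode the visual noise scale is `exp(d / k)` where `d` is the
#' fixation-to-target distance; this emulates the loss of acuity away from
#' the fovea. In uniform mode the visual noise is exactly zero.
#'
#' @param mode `"uniform"` or `"nonuniform"`.
#' @param k Positive scaling factor (default 1.5).
#' @param sigma_as_variance If `TRUE`, `exp(d/k)` is interpreted as the noise
#'   variance rather than its standard deviation (sensitivity switch).
#' @return List noise model.
#' @export
fovea_noise <- function(mode = c("nonuniform", "uniform"), k = 1.5,
                        sigma_as_variance = FALSE) {
  mode <- match.arg(mode)
  stopifnot(k > 0)
  list(mode = mode, k = k, sigma_as_variance = sigma_as_variance)
}

#' Visual noise standard deviation at a given eccentricity
#'
#' @param d Nonnegative distance between fixation point and target.
#' @param noise Noise model from [fovea_noise()].
#' @return Standard deviation of the Gaussian error added to each eye's image
#'   coordinate (0 in uniform mode).
#' @export
fovea_sigma <- function(d, noise) {
  stopifnot(d >= 0)
  if (noise$mode == "uniform") return(0)
  s <- exp(d / noise$k)
  if (isTRUE(noise$sigma_as_variance)) sqrt(s) else s
}

#' Point of fixation of the two eyes
#'
#' Intersection of the two gaze rays. Eye `i` at `(0, l_i)` with absolute
#' angle `theta_i` gazes along the ray `y = l_i + x * tan(theta_i)`, `x > 0`.
#' When the rays are parallel or intersect behind the eyes (non-converging
#' gaze) the fixation point is placed `far_clip` world units from the origin
#' along the mean gaze direction, so the eccentricity distance is always
#' finite.
#'
#' @param world World state from [world_state()].
#' @param far_clip Fallback fixation distance.
#' @return List with `point` (numeric 2-vector) and `converged` (logical,
#'   `FALSE` when the far-clip fallback was used).
#' @export
fixation_point <- function(world, far_clip = 8) {
  th <- eye_angles_abs(world$eye_angles[1], world$eye_angles[2])
  l <- eye_offsets(world$L)
  t0 <- tan(th[1]); t1 <- tan(th[2])
  if (abs(t1 - t0) > 1e-12) {
    x <- (l[1] - l[2]) / (t1 - t0)
    if (x > 0) {
      y <- l[1] + x * t0
      return(list(point = c(x, y), converged = TRUE))
    }
  }
  ta <- world$eye_angles[1]
  list(point = far_clip * c(cos(ta), sin(ta)), converged = FALSE)
}

# noiseless image coordinate of the target in eye i's camera
true_projection <- function(world, eye) {
  th <- eye_angles_abs(world$eye_angles[1], world$eye_angles[2])[eye + 1]
  l <- eye_offsets(world$L)[eye + 1]
  r <- apply_transform(make_eye_transform(th, l), c(world$target, 1))
  if (r[1] <= 0) stop("target behind eye ", eye, ": observation invalid")
  project_to_camera(r, world$f)[2]
}

#' Generate one observation from the generative process
#'
#' Proprioception `sp` is a noiseless identity readout of the true
#' vergence-accommodation angles. Each eye's visual observation `sv[i]` is
#' the true pinhole projection of the target plus Gaussian noise whose
#' standard deviation follows [fovea_sigma()] at the current
#' fixation-to-target distance. Noise is drawn from R's RNG stream; seed the
#' session for reproducibility.
#'
#' @param world World state.
#' @param noise Noise model from [fovea_noise()].
#' @param far_clip Fallback fixation distance for non-converging gaze.
#' @return List with `sp` (2-vector), `sv` (2-vector, one coordinate per
#'   eye), `sigma` (noise sd used), and `d` (fixation-to-target distance).
#' @export
observe <- function(world, noise, far_clip = 8) {
  if (!all(is.finite(world$eye_angles))) stop("observation invalid: non-finite eye angles")
  fix <- fixation_point(world, far_clip)
  d <- sqrt(sum((fix$point - world$target)^2))
  sigma <- fovea_sigma(d, noise)
  if (!is.finite(sigma)) stop("observation invalid: non-finite noise scale")
  sv <- vapply(0:1, function(i) true_projection(world, i), numeric(1))
  if (sigma > 0) sv <- sv + stats::rnorm(2L, 0, sigma)
  list(sp = world$eye_angles, sv = sv, sigma = sigma, d = d)
}

#' Advance the true eye angles under a motor command
#'
#' `(theta_a, theta_v) <- (theta_a, theta_v) + dt * a`, with the resulting
#' absolute per-eye angles kept inside `(-angle_limit, angle_limit)` by
#' clipping the pair, so targets stay in front of the eyes. The target never
#' moves.
#'
#' @param world World state.
#' @param a Numeric 2-vector of angular velocities (action signal).
#' @param dt Integration step.
#' @param angle_limit Clipping bound on the absolute per-eye angles.
#' @return Updated world state.
#' @export
apply_action <- function(world, a, dt, angle_limit = pi / 2) {
  ang <- world$eye_angles + dt * a
  # clip in terms of the absolute per-eye angles theta_a -/+ theta_v
  th <- eye_angles_abs(ang[1], ang[2])
  eps <- 1e-6
  th <- pmin(pmax(th, -angle_limit + eps), angle_limit - eps)
  world$eye_angles <- c((th[1] + th[2]) / 2, (th[2] - th[1]) / 2)
  world
}

# vergence-accommodation pair that fixates a target exactly
fixation_angles <- function(target, L) {
  l <- eye_offsets(L)
  # eye i fixates when -sin(th)*x + cos(th)*(y - l_i) = 0
  th0 <- atan((target[2] - l[1]) / target[1])
  th1 <- atan((target[2] - l[2]) / target[1])
  c((th0 + th1) / 2, (th1 - th0) / 2)
}
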