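# Generic continuous-time predictive-coding machinery: beliefs in generalized
# coordinates (value + first derivative), dynamic prediction-error units,
# the action update, and a free-energy monitoring proxy. Integration is
# explicit Euler; each operation takes the step dt so callers can scale
# per-unit learning rates by passing an effective step.

#' Create a dynamic prediction-error unit
#'
#' Error units are first-order states that relax toward the precision-weighted
#' raw error: `d(value)/dt = raw_error - value / precision`, with fixed point
#' `precision * raw_error` for constant input. Precision is the inverse
#' variance the agent assigns to that pathway.
#'
#' @param value Initial error value (numeric vector or scalar).
#' @param precision Positive scalar precision.
#' @return List with elements `value` and `precision`.
#' @export
error_unit <- function(value = 0, precision = 1) {
  if (!is.numeric(precision) || any(precision <= 0))
    stop("error-unit precision must be positive")
  list(value = value, precision = precision)
}

#' One Euler step of an error unit
#'
#' @param eu Error unit from [error_unit()].
#' @param raw_error Raw (unweighted) prediction error, same shape as the value.
#' @param dt Integration step; must satisfy `dt < 2 * precision` for stability
#'   of the scalar linear relaxation.
#' @return Updated error unit.
#' @export
step_error_unit <- function(eu, raw_error, dt) {
  eu$value <- eu$value + dt * (raw_error - eu$value / eu$precision)
  eu
}

#' Create a belief in generalized coordinates
#'
#' A belief carries two temporal orders, the value `mu` and its expected
#' first derivative `mu_p`, plus a dynamics function `f(mu)` predicting the
#' derivative and the precision `gamma` of that dynamics model. A frozen
#' belief ignores all updates (used to gate the absolute-position belief
#' during action phases).
#'
#' @param mu Initial value (numeric vector).
#' @param mu_p Initial first order (defaults to zeros).
#' @param dynamics_fn Function `mu -> predicted derivative`; default constant 0.
#' @param gamma Positive dynamics precision.
#' @param frozen Logical; frozen beliefs are left unchanged by [step_belief()].
#' @return List with elements `mu`, `mu_p`, `dynamics_fn`, `gamma`, `frozen`.
#' @export
gen_belief <- function(mu, mu_p = NULL, dynamics_fn = NULL, gamma = 1,
                       frozen = FALSE) {
  if (is.null(mu_p)) mu_p <- numeric(length(mu))
  if (is.null(dynamics_fn)) dynamics_fn <- function(mu) numeric(length(mu))
  list(mu = mu, mu_p = mu_p, dynamics_fn = dynamics_fn, gamma = gamma,
       frozen = frozen)
}

#' One Euler step of a generalized belief
#'
#' Follows the first-order pattern of the belief update equations: the zeroth
#' order moves with its expected derivative plus the precision-weighted error
#' gradients climbing from below (`bottom_up`) and descending from above
#' (`top_down`); the first order is corrected by the dynamics prediction
#' error.
#'
#' @param b Belief from [gen_belief()].
#' @param bottom_up Sum of likelihood error gradients (same shape as `mu`).
#' @param top_down Sum of prior error gradients (same shape as `mu`).
#' @param dyn_error Dynamics prediction-error value applied (negatively) to
#'   the first order.
#' @param dt Integration step.
#' @return Updated belief; a frozen belief is returned untouched.
#' @export
step_belief <- function(b, bottom_up = 0, top_down = 0, dyn_error = 0, dt = 0.01) {
  if (isTRUE(b$frozen)) return(b)
  b$mu <- b$mu + dt * (b$mu_p + bottom_up + top_down)
  b$mu_p <- b$mu_p + dt * (-dyn_error)
  b
}

#' Create a motor action state
#'
#' @param a Initial control signal (angular velocity units).
#' @param gain Positive learning rate of the action update.
#' @param enabled Logical; a disabled action is treated as zero and never
#'   updated.
#' @return List with elements `a`, `gain`, `enabled`.
#' @export
action_state <- function(a = 0, gain = 1, enabled = TRUE) {
  list(a = a, gain = gain, enabled = enabled)
}

#' One Euler step of the action update
#'
#' Gradient descent of the proprioceptive free energy on the control signal:
#' `a <- a - dt * gain * t(jac) %*% (precision * error)`. With the identity
#' proprioceptive map the Jacobian is the identity.
#'
#' @param act Action state from [action_state()].
#' @param proprio_error Proprioceptive error unit.
#' @param jac Jacobian of the proprioceptive observation with respect to the
#'   control signal (matrix or scalar; default identity).
#' @param dt Integration step.
#' @return Updated action state; disabled actions are returned untouched.
#' @export
step_action <- function(act, proprio_error, jac = 1, dt = 0.01) {
  if (!isTRUE(act$enabled)) return(act)
  weighted <- proprio_error$precision * proprio_error$value
  grad <- if (is.matrix(jac)) as.numeric(crossprod(jac, weighted)) else jac * weighted
  act$a <- act$a - dt * act$gain * grad
  act
}

#' Precision-weighted squared-error proxy for the variational free energy
#'
#' Returns `0.5 * sum_k precision_k * ||raw_error_k||^2`, a nonnegative
#' monitoring scalar that is zero exactly when all raw errors vanish. It is
#' the Laplace-form bound up to state-independent terms and is used to track
#' minimization progress, not to drive updates.
#'
#' @param error_units List of error units (their precisions are used).
#' @param raw_errors List of raw error vectors, same length.
#' @return Nonnegative scalar.
#' @export
free_energy_proxy <- function(error_units, raw_errors) {
  stopifnot(length(error_units) == length(raw_errors))
  total <- 0
  for (k in seq_along(error_units)) {
    total <- total + sum(error_units[[k]]$precision * raw_errors[[k]]^2)
  }
  0.5 * total
}
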