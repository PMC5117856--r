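#' Physical parameters of the single-degree-of-freedom arm
#'
#' Bundles the constants of the shoulder-rotation dynamics: the whole-arm
#' segment mass \eqn{m}, the shoulder-to-centre-of-mass lever arm \eqn{l},
#' the moment of inertia about the shoulder \eqn{I}, the viscous friction
#' coefficient \eqn{B}, and the gravitational acceleration \eqn{g}.
#'
#' `gravity` defaults to 9.81 m/s^2 and may be set to any value, including
#' 0 (microgravity) or a negative value when it plays the role of a planner's
#' internal gravity estimate being fitted.
#'
#' @param arm_mass Whole-arm segment mass (kg), > 0.
#' @param lever_arm Distance from the shoulder to the segment centre of mass
#'   (m), > 0.
#' @param inertia Moment of inertia about the shoulder (kg m^2), > 0.
#' @param friction Viscous friction coefficient (N m s/rad), >= 0.
#'   Default 0.87.
#' @param gravity Gravitational acceleration (m/s^2). Default 9.81.
#'
#' @return An object of class `arm_parameters` (a named list).
#' @seealso [anthropometrics_from_body()] to derive `arm_mass`, `lever_arm`
#'   and `inertia` from body mass and arm length.
#' @export
#' @examples
#' arm_parameters(arm_mass = 3.5, lever_arm = 0.37, inertia = 0.71)
arm_parameters <- function(arm_mass, lever_arm, inertia,
                           friction = 0.87, gravity = 9.81) {
  stopifnot(
    is.numeric(arm_mass), length(arm_mass) == 1L, is.finite(arm_mass),
    is.numeric(lever_arm), length(lever_arm) == 1L, is.finite(lever_arm),
    is.numeric(inertia), length(inertia) == 1L, is.finite(inertia),
    is.numeric(friction), length(friction) == 1L, is.finite(friction),
    is.numeric(gravity), length(gravity) == 1L, is.finite(gravity)
  )
  if (arm_mass <= 0) stop("`arm_mass` must be > 0")
  if (lever_arm <= 0) stop("`lever_arm` must be > 0")
  if (inertia <= 0) stop("`inertia` must be > 0")
  if (friction < 0) stop("`friction` must be >= 0")
  structure(
    list(arm_mass = arm_mass, lever_arm = lever_arm, inertia = inertia,
         friction = friction, gravity = gravity),
    class = "arm_parameters"
  )
}

#' @export
print.arm_parameters <- function(x, ...) {
  cat("Single-DOF arm parameters\n")
  cat(sprintf("  arm mass   m = %.4g kg\n", x$arm_mass))
  cat(sprintf("  lever arm  l = %.4g m\n", x$lever_arm))
  cat(sprintf("  inertia    I = %.4g kg m^2\n", x$inertia))
  cat(sprintf("  friction   B = %.4g N m s/rad\n", x$friction))
  cat(sprintf("  gravity    g = %.4g m/s^2\n", x$gravity))
  invisible(x)
}

# Whole-arm segment coefficients (Winter-style anthropometric table):
# mass fraction of body mass, centre-of-mass fraction of arm length measured
# from the shoulder, and radius-of-gyration fraction about the proximal end.
ARM_SEGMENT_COEFFICIENTS <- c(
  mass_fraction     = 0.050,
  com_fraction      = 0.530,
  gyration_fraction = 0.645
)

#' Estimate arm parameters from body mass and arm length
#'
#' Applies whole-arm segment coefficients from a standard anthropometric
#' table: segment mass as a fraction of body mass, centre of mass as a
#' fraction of arm length from the shoulder, and radius of gyration about
#' the shoulder as a fraction of arm length (so
#' \eqn{I = m (k_g L)^2}). Each coefficient can be overridden.
#'
#' @param body_mass Body mass (kg), > 0.
#' @param arm_length Shoulder-to-fingertip arm length (m), > 0.
#' @param coefficients Named numeric vector with entries `mass_fraction`,
#'   `com_fraction`, `gyration_fraction`. Defaults to the package's
#'   whole-arm table values (0.050, 0.530, 0.645).
#' @param friction,gravity Passed to [arm_parameters()].
#'
#' @return An `arm_parameters` object.
#' @export
#' @examples
#' anthropometrics_from_body(body_mass = 70, arm_length = 0.70)
anthropometrics_from_body <- function(body_mass, arm_length,
                                      coefficients = ARM_SEGMENT_COEFFICIENTS,
                                      friction = 0.87, gravity = 9.81) {
  stopifnot(is.numeric(body_mass), length(body_mass) == 1L,
            is.numeric(arm_length), length(arm_length) == 1L)
  if (!is.finite(body_mass) || body_mass <= 0) {
    stop("`body_mass` must be a positive finite number")
  }
  if (!is.finite(arm_length) || arm_length <= 0) {
    stop("`arm_length` must be a positive finite number")
  }
  co <- ARM_SEGMENT_COEFFICIENTS
  co[names(coefficients)] <- coefficients
  m <- co[["mass_fraction"]] * body_mass
  arm_parameters(
    arm_mass  = m,
    lever_arm = co[["com_fraction"]] * arm_length,
    inertia   = m * (co[["gyration_fraction"]] * arm_length)^2,
    friction  = friction,
    gravity   = gravity
  )
}

#' Define a rest-to-rest movement task
#'
#' A planned single-joint shoulder rotation from a static initial posture to
#' a static final posture in a plane inclined by `gamma` relative to
#' horizontal. The shoulder angle theta is measured from the initial
#' (horizontal-arm) posture and increases toward the target. Sign
#' convention for the plane inclination: `gamma = -pi/2` is a straight
#' upward movement, `gamma = +pi/2` straight downward, `gamma = 0`
#' horizontal.
#'
#' @param theta_start Shoulder angle at movement onset (rad). Default 0.
#' @param theta_end Shoulder angle at movement offset (rad).
#'   Default `pi/4` (a 45 degree rotation).
#' @param gamma Plane-of-motion inclination relative to horizontal (rad),
#'   in `[-pi/2, pi/2]`. Default 0.
#' @param duration Movement time T (s), > 0. Default 0.40.
#'
#' @return An object of class `movement_task` with the derived field
#'   `amplitude = abs(theta_end - theta_start)`.
#' @export
#' @examples
#' movement_task(gamma = -pi / 2)          # 45 degree upward rotation
#' movement_task(gamma = pi / 2, duration = 0.5)
movement_task <- function(theta_start = 0, theta_end = pi / 4,
                          gamma = 0, duration = 0.40) {
  stopifnot(is.numeric(theta_start), is.numeric(theta_end),
            is.numeric(gamma), is.numeric(duration),
            length(theta_start) == 1L, length(theta_end) == 1L,
            length(gamma) == 1L, length(duration) == 1L)
  if (!all(is.finite(c(theta_start, theta_end, gamma, duration)))) {
    stop("movement task fields must be finite")
  }
  if (duration <= 0) stop("`duration` must be > 0")
  amplitude <- abs(theta_end - theta_start)
  if (amplitude <= 0) stop("movement amplitude must be > 0")
  if (gamma < -pi / 2 - 1e-12 || gamma > pi / 2 + 1e-12) {
    stop("`gamma` must lie in [-pi/2, pi/2]")
  }
  structure(
    list(theta_start = theta_start, theta_end = theta_end,
         gamma = gamma, duration = duration, amplitude = amplitude),
    class = "movement_task"
  )
}

#' @export
print.movement_task <- function(x, ...) {
  cat(sprintf(
    "Movement task: %.1f deg -> %.1f deg, plane %.1f deg, T = %.3g s\n",
    x$theta_start * 180 / pi, x$theta_end * 180 / pi,
    x$gamma * 180 / pi, x$duration))
  invisible(x)
}

#' Gravity torque projected on the plane of motion
#'
#' Computes \eqn{GT(\theta, \gamma) = m g l \cos\theta \sin\gamma}, the
#' component of the gravitational torque acting in the plane of motion.
#' Positive values act in the direction of movement (toward the target), so
#' GT is positive for downward plane inclinations (`gamma > 0`): gravity
#' assists the motion.
#'
#' @param theta Shoulder angle(s) from the horizontal initial posture (rad);
#'   vectorised.
#' @param gamma Plane inclination (rad).
#' @param params An [arm_parameters()] object.
#'
#' @return Gravity torque (N m), same length as `theta`.
#' @export
#' @examples
#' p <- anthropometrics_from_body(70, 0.70)
#' gravity_torque(seq(0, pi / 4, length.out = 5), gamma = pi / 2, p)
gravity_torque <- function(theta, gamma, params) {
  stopifnot(inherits(params, "arm_parameters"), is.numeric(theta),
            is.numeric(gamma), length(gamma) == 1L)
  if (!all(is.finite(theta)) || !is.finite(gamma)) {
    stop("`theta` and `gamma` must be finite")
  }
  params$arm_mass * params$gravity * params$lever_arm *
    cos(theta) * sin(gamma)
}

#' Work of the gravity torque over a movement
#'
#' Integrates the gravity torque over the movement amplitude,
#' \eqn{WGT = \int_0^{A} GT(\theta,\gamma)\, d\theta
#'          = m g l \sin\gamma\,[\sin\theta]_{\theta_0}^{\theta_f}},
#' evaluated in closed form. Positive values mean the work of gravity acts
#' in the movement direction (gravity assists, downward inclinations);
#' negative values mean gravity opposes the movement (upward inclinations).
#'
#' @param task A [movement_task()].
#' @param params An [arm_parameters()] object.
#'
#' @return Work of gravity torque (J, scalar).
#' @export
#' @examples
#' p <- anthropometrics_from_body(70, 0.70)
#' work_of_gravity_torque(movement_task(gamma = pi / 2), p)   # assists
#' work_of_gravity_torque(movement_task(gamma = -pi / 2), p)  # opposes
work_of_gravity_torque <- function(task, params) {
  stopifnot(inherits(task, "movement_task"),
            inherits(params, "arm_parameters"))
  params$arm_mass * params$gravity * params$lever_arm * sin(task$gamma) *
    (sin(task$theta_end) - sin(task$theta_start))
}

#' Default set of movement directions
#'
#' Evenly spaced plane inclinations spanning straight up (-90 deg) to
#' straight down (+90 deg), mirroring a frontal-plane target array.
#'
#' @param n Number of directions (default 17).
#' @param degrees Return degrees instead of radians? Default `FALSE`.
#' @return Numeric vector of `n` inclinations.
#' @export
#' @examples
#' direction_set(17, degrees = TRUE)
direction_set <- function(n = 17, degrees = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  g <- seq(-pi / 2, pi / 2, length.out = as.integer(n))
  if (degrees) g * 180 / pi else g
}
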