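#' Solve the Smooth-Effort optimal trajectory
#'
#' Minimizes the hybrid cost
#' \deqn{C = \int_0^T |\tau \dot\theta|\,dt +
#'       \alpha \int_0^T \dddot\theta^2\,dt}
#' (absolute work of the net muscle torque, plus squared angular jerk
#' weighted by `alpha`) subject to the single-joint dynamics
#' \eqn{\tau = I\ddot\theta + B\dot\theta - GT(\theta,\gamma)},
#' rest-to-rest boundary conditions with static boundary torque, and fixed
#' movement duration. The absolute value is smoothed as
#' `sqrt(x^2 + effort_smoothing^2)` with a continuation over decreasing
#' smoothing widths.
#'
#' Because the effort term is torque-dependent, the optimal velocity
#' profile is direction-dependent under gravity: peak velocity occurs
#' earlier for upward than for downward movements (SR below/above 0.5),
#' and this asymmetry vanishes when `params$gravity = 0`.
#'
#' @param task A [movement_task()].
#' @param params An [arm_parameters()] object.
#' @param spec A [cost_spec()] with `model = "smooth_effort"`.
#' @param init Initialization: `"minjerk"` (default), `"cosine"`, or a
#'   numeric coefficient vector.
#' @return An `arm_trajectory`.
#' @export
#' @examples
#' p <- anthropometrics_from_body(70, 0.70)
#' tr_up <- solve_smooth_effort(movement_task(gamma = -pi / 2), p)
#' tr_dn <- solve_smooth_effort(movement_task(gamma = pi / 2), p)
#' c(up = trajectory_sr(tr_up), down = trajectory_sr(tr_dn))
solve_smooth_effort <- function(task, params,
                                spec = cost_spec("smooth_effort"),
                                init = "minjerk") {
  stopifnot(inherits(task, "movement_task"),
            inherits(params, "arm_parameters"),
            inherits(spec, "cost_spec"))
  if (spec$model != "smooth_effort") {
    stop("`spec$model` must be 'smooth_effort'")
  }
  solve_ritz(task, params, "smooth_effort", spec, init)
}

#' Solve the minimum-jerk trajectory (closed form)
#'
#' The rest-to-rest minimizer of \eqn{\int_0^T \dddot\theta^2 dt} is the
#' classical quintic polynomial, independent of arm dynamics and movement
#' direction. Its speed profile is exactly symmetric (SR = 0.5) with peak
#' speed `(15/8) * amplitude / T` at `t = T/2`.
#'
#' @param task A [movement_task()].
#' @param n_out Number of output grid nodes. Default 401.
#' @return An `arm_trajectory` with `torque = NA` (dynamics-independent
#'   model; use [solve_min_jerk_torque()] if torque under given dynamics is
#'   needed).
#' @export
#' @examples
#' tr <- solve_min_jerk(movement_task())
#' max(abs(tr$velocity)) * 0.4 / (pi / 4)  # 15/8
solve_min_jerk <- function(task, n_out = 401) {
  stopifnot(inherits(task, "movement_task"))
  s <- seq(0, 1, length.out = n_out)
  mj <- minjerk_shape(s)
  D <- task$theta_end - task$theta_start
  T <- task$duration
  new_trajectory(
    times = s * T,
    angle = task$theta_start + D * mj$q0,
    velocity = D * mj$q1 / T,
    acceleration = D * mj$q2 / T^2,
    torque = rep(NA_real_, n_out),
    jerk = D * mj$q3 / T^3,
    model = "jerk",
    cost_value = 720 * D^2 / T^5,  # closed-form integral of squared jerk
    task = task
  )
}

#' Minimum-jerk trajectory with torque under given dynamics
#'
#' Convenience wrapper: the minimum-jerk kinematics of [solve_min_jerk()]
#' with the net muscle torque implied by the arm dynamics filled in.
#'
#' @inheritParams solve_smooth_effort
#' @param n_out Number of output grid nodes.
#' @return An `arm_trajectory`.
#' @export
solve_min_jerk_torque <- function(task, params, n_out = 401) {
  tr <- solve_min_jerk(task, n_out)
  tr$torque <- torque_from_kinematics(tr$angle, tr$velocity,
                                      tr$acceleration, task, params)
  tr
}

#' Solve the minimum torque-change trajectory
#'
#' Minimizes \eqn{\int_0^T (d\tau/dt)^2 dt} subject to the single-joint
#' dynamics and rest-to-rest boundary conditions. With zero gravity and
#' zero friction the torque is proportional to acceleration and the
#' solution coincides with the minimum-jerk quintic. Under gravity, the
#' predicted speed profiles remain nearly symmetric in all directions:
#' direction-dependent asymmetry is specific to effort-like costs.
#'
#' @inheritParams solve_smooth_effort
#' @param spec A [cost_spec()]; its `n_basis`, `n_quad`, `n_out` control
#'   the transcription.
#' @return An `arm_trajectory`.
#' @export
solve_torque_change <- function(task, params,
                                spec = cost_spec("torque_change"),
                                init = "minjerk") {
  stopifnot(inherits(task, "movement_task"),
            inherits(params, "arm_parameters"),
            inherits(spec, "cost_spec"))
  solve_ritz(task, params, "torque_change", spec, init)
}

#' Evaluate the torque-change cost of a trajectory
#'
#' \eqn{\int_0^T (d\tau/dt)^2 dt} by trapezoidal quadrature of the torque
#' rate computed from the trajectory's kinematics and the arm dynamics.
#' Useful as an optimality cross-check (any feasible trajectory must cost
#' at least as much as the optimum).
#'
#' @param traj An `arm_trajectory` (with `task` attached).
#' @param params An [arm_parameters()] object.
#' @return Scalar cost value.
#' @export
torque_change_cost <- function(traj, params) {
  stopifnot(inherits(traj, "arm_trajectory"), !is.null(traj$task))
  task <- traj$task
  mgl_sg <- params$arm_mass * params$gravity * params$lever_arm *
    sin(task$gamma)
  u <- params$inertia * traj$jerk + params$friction * traj$acceleration +
    mgl_sg * sin(traj$angle) * traj$velocity
  h <- diff(traj$times)
  sum(h * (u[-length(u)]^2 + u[-1]^2) / 2)
}
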