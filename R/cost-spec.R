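#' Specify the cost model and solver settings for trajectory optimization
#'
#' @param model One of `"smooth_effort"`, `"jerk"`, `"torque_change"`,
#'   `"variance"`, `"variance_muscle"`.
#' @param alpha Weight of the squared-jerk (smoothness) term in the hybrid
#'   Smooth-Effort cost (dimensionless). Default `7e-5`.
#' @param noise_scale Signal-dependent noise scale of the minimum-variance
#'   model: the control-noise variance at step t is
#'   `noise_scale * u_t^2`. Default 0.2.
#' @param dt Discretization step of the minimum-variance models (s).
#'   Default 0.010; must divide the movement duration evenly.
#' @param post_time Post-movement stabilization horizon in steps. `NULL`
#'   (default) means equal to the number of movement steps.
#' @param muscle_gain Torque produced by full agonist activation (N m) in
#'   the muscle-dynamics variance model. Default 60.
#' @param muscle_tau Time constant of the first-order muscle filter (s).
#'   Default 0.05.
#' @param effort_smoothing Smoothing width for the absolute value in the
#'   effort cost: `|x|` is replaced by `sqrt(x^2 + effort_smoothing^2)`.
#'   In cost-rate units (W). Default `1e-6`.
#' @param n_basis Number of polynomial basis functions of the trajectory
#'   parameterization. Default 14.
#' @param n_quad Number of Gauss-Legendre quadrature nodes used to evaluate
#'   the cost integrals. Default 120.
#' @param n_out Number of output grid nodes of the returned trajectory.
#'   Default 401.
#'
#' @return An object of class `cost_spec`.
#' @export
#' @examples
#' cost_spec("smooth_effort")
#' cost_spec("variance", dt = 0.01)
cost_spec <- function(model = c("smooth_effort", "jerk", "torque_change",
                                "variance", "variance_muscle"),
                      alpha = 7e-5, noise_scale = 0.2, dt = 0.010,
                      post_time = NULL, muscle_gain = 60,
                      muscle_tau = 0.05, effort_smoothing = 1e-6,
                      n_basis = 14, n_quad = 120, n_out = 401) {
  model <- match.arg(model)
  stopifnot(alpha >= 0, noise_scale >= 0, dt > 0, effort_smoothing > 0,
            muscle_gain > 0, muscle_tau > 0,
            n_basis >= 4, n_quad >= 20, n_out >= 50)
  if (!is.null(post_time)) stopifnot(post_time >= 1)
  structure(
    list(model = model, alpha = alpha, noise_scale = noise_scale, dt = dt,
         post_time = post_time, muscle_gain = muscle_gain,
         muscle_tau = muscle_tau, effort_smoothing = effort_smoothing,
         n_basis = n_basis, n_quad = n_quad, n_out = n_out),
    class = "cost_spec"
  )
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("<cost_spec> model = %s\n", x$model))
  invisible(x)
}
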