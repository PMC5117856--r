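# Statistical layer: sigmoid tuning-curve fits, SR-vs-WGT correlation,
# model SR curves, and recovery of the planner's internal gravity value
# from directional velocity-profile asymmetries.

#' Fit a four-parameter sigmoid tuning curve
#'
#' Nonlinear least squares of the logistic
#' \deqn{F(x) = p_1 + p_2 / (1 + \exp(-(x - p_3)/p_4))}
#' (offset, range, midpoint, slope scale) by Levenberg-Marquardt, with a
#' deterministic multi-start over midpoint and slope-scale guesses; the
#' best fit by residual sum of squares is kept. Goodness of fit is
#' reported as the root-mean-square error in the units of `y`.
#'
#' @param x Predictor (e.g. direction angle in degrees), strictly
#'   increasing, length >= 5.
#' @param y Response (e.g. symmetry ratio), same length.
#' @return An object of class `sigmoid_fit`: list with `p1`, `p2`, `p3`,
#'   `p4`, `rmse`, `fitted`, and `predict` (a function of x).
#' @export
#' @examples
#' x <- seq(-90, 90, length.out = 17)
#' y <- 0.42 + 0.12 / (1 + exp(-(x - 5) / 25))
#' f <- fit_sigmoid(x, y)
#' c(f$p3, f$rmse)
fit_sigmoid <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 5)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  ry <- diff(range(y))
  rx <- diff(range(x))

  if (ry < 1e-12) {
    # degenerate plateau: exact fit with zero range
    p <- c(p1 = mean(y), p2 = 0, p3 = mean(x), p4 = rx / 5)
    return(new_sigmoid_fit(p, x, y))
  }

  starts <- expand.grid(
    p3 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    p4 = c(rx / 10, rx / 5, rx / 2, -rx / 5)
  )
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(p1 = min(y), p2 = ry, p3 = starts$p3[i], p4 = starts$p4[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ p1 + p2 / (1 + exp(-(x - p3) / p4)),
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("sigmoid fit failed to converge from all starting points; ",
         sprintf("y range %.3g over x range %.3g", ry, rx))
  }
  new_sigmoid_fit(stats::coef(best), x, y)
}

new_sigmoid_fit <- function(p, x, y) {
  p <- as.list(p)
  predict_fn <- function(xx) {
    p$p1 + p$p2 / (1 + exp(-(xx - p$p3) / p$p4))
  }
  fitted <- predict_fn(x)
  structure(
    list(p1 = p$p1, p2 = p$p2, p3 = p$p3, p4 = p$p4,
         rmse = sqrt(mean((y - fitted)^2)),
         fitted = fitted, predict = predict_fn),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> offset %.4g, range %.4g, midpoint %.4g, scale %.4g (RMSE %.3g)\n",
    x$p1, x$p2, x$p3, x$p4, x$rmse))
  invisible(x)
}

#' Pearson correlation with input validation
#'
#' Pearson product-moment correlation of two equal-length, non-constant
#' numeric vectors; constant input raises an explicit error rather than
#' returning `NA`.
#'
#' @param x,y Numeric vectors, equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Model-predicted symmetry-ratio tuning curve
#'
#' Maps each movement direction to the symmetry ratio of the model-optimal
#' trajectory, together with the work of gravity torque for that
#' direction. Deterministic given the configuration.
#'
#' @param params An [arm_parameters()] object.
#' @param spec A [cost_spec()]; its `model` selects the solver.
#' @param directions Plane inclinations (rad). Default
#'   `direction_set(17)`.
#' @param duration Movement time (s). Default 0.40.
#' @param amplitude Movement amplitude (rad). Default `pi/4`.
#' @param use_cache Reuse memoized Smooth-Effort solves? Default `TRUE`.
#' @return A tibble with columns `gamma` (deg), `sr`, `wgt` (J), `model`.
#' @export
#' @examples
#' p <- anthropometrics_from_body(70, 0.70)
#' predict_sr_curve(p, cost_spec("jerk"), direction_set(5))
predict_sr_curve <- function(params, spec = cost_spec("smooth_effort"),
                             directions = direction_set(17),
                             duration = 0.40, amplitude = pi / 4,
                             use_cache = TRUE) {
  stopifnot(inherits(params, "arm_parameters"), inherits(spec, "cost_spec"))
  rows <- lapply(directions, function(g) {
    task <- movement_task(theta_start = 0, theta_end = amplitude,
                          gamma = g, duration = duration)
    tr <- tryCatch(
      switch(spec$model,
        smooth_effort = if (use_cache) cached_smooth_effort(task, params,
                                                            spec) else
          solve_smooth_effort(task, params, spec),
        jerk = solve_min_jerk(task),
        torque_change = solve_torque_change(task, params, spec),
        variance = solve_min_variance(task, params, spec)$trajectory,
        variance_muscle =
          solve_min_variance_muscle(task, params, spec)$trajectory),
      error = function(e) {
        stop(sprintf("solver failed at gamma = %.1f deg: %s",
                     g * 180 / pi, conditionMessage(e)))
      })
    tibble::tibble(
      gamma = g * 180 / pi,
      sr = trajectory_sr(tr),
      wgt = work_of_gravity_torque(task, params),
      model = spec$model)
  })
  dplyr::bind_rows(rows)
}

# Model-predicted SR difference (down minus up) at internal gravity g,
# memoized package-wide. Reversing the sign of gravity swaps the roles of
# the up and down tasks exactly, so negative g is evaluated by mirroring.
predict_sr_diff <- function(g, params, spec, task_up, task_down) {
  if (g < 0) {
    return(-predict_sr_diff(-g, params, spec, task_up, task_down))
  }
  pg <- params
  pg$gravity <- g
  sr_up <- trajectory_sr(cached_smooth_effort(task_up, pg, spec))
  sr_down <- trajectory_sr(cached_smooth_effort(task_down, pg, spec))
  sr_down - sr_up
}

#' Recover the planner's internal gravity from an observed SR asymmetry
#'
#' Bounded scalar fit of the gravity value g used by the Smooth-Effort
#' planner: finds g in `bounds` minimizing the squared deviation between
#' the model-predicted symmetry-ratio difference (down minus up, from two
#' Smooth-Effort solves at gravity g) and the observed difference. Uses a
#' coarse-to-fine search on a quantized g grid so repeated fits share
#' memoized trajectory solves.
#'
#' @param observed_sr_diff Observed `SR_down - SR_up` (dimensionless,
#'   finite).
#' @param params An [arm_parameters()] object (its `gravity` is ignored).
#' @param spec A [cost_spec()] for the Smooth-Effort solves.
#' @param task_up,task_down The up and down movement tasks. Defaults:
#'   45 degree rotations at `gamma = -pi/2` and `+pi/2`, 0.40 s.
#' @param bounds Search bounds for g (m/s^2). Default
#'   `c(-2, 2) * 9.81`.
#' @param init Prior guess used to select among equally well-fitting
#'   candidate g values (the predicted SR difference is not injective in
#'   g: the asymmetry rises steeply at low gravity, peaks, and vanishes
#'   again when gravity torque dominates, so an observed difference can
#'   have two preimages). Default 9.81, the Earth-gravity prior.
#' @param resolution Quantization of candidate g values (m/s^2).
#'   Default 0.05.
#' @param coarse_step Step of the global scan grid (m/s^2). Default 0.5.
#' @param tie_tolerance Objective margin (squared SR units) within which
#'   candidate minima count as ties resolved by proximity to `init`.
#'   Default `1e-4`.
#' @return A list of class `adaptation_fit`: `fitted_g`,
#'   `observed_sr_diff`, `predicted_sr_diff`, `objective`.
#' @export
#' @examples
#' \donttest{
#' p <- anthropometrics_from_body(70, 0.70)
#' fit_internal_g(0.14, p)$fitted_g
#' }
fit_internal_g <- function(observed_sr_diff, params,
                           spec = cost_spec("smooth_effort"),
                           task_up = movement_task(gamma = -pi / 2),
                           task_down = movement_task(gamma = pi / 2),
                           bounds = c(-2, 2) * 9.81,
                           init = 9.81, resolution = 0.05,
                           coarse_step = 0.5, tie_tolerance = 1e-4) {
  stopifnot(is.finite(observed_sr_diff), length(bounds) == 2,
            bounds[1] < bounds[2], resolution > 0,
            coarse_step > resolution)
  quant <- function(g) {
    pmin(bounds[2], pmax(bounds[1], round(g / resolution) * resolution))
  }
  obj <- function(g) {
    (predict_sr_diff(g, params, spec, task_up, task_down) -
       observed_sr_diff)^2
  }
  # global scan on a fixed quantized grid (memoized across calls)
  gs <- unique(quant(seq(bounds[1], bounds[2], by = coarse_step)))
  vals <- vapply(gs, obj, numeric(1))
  # local minima of the scanned objective
  n <- length(vals)
  is_min <- vals <= c(Inf, vals[-n]) & vals <= c(vals[-1], Inf)
  cand <- which(is_min & vals <= min(vals) + tie_tolerance)
  # ties resolved by proximity to the prior (compared at 1 m/s^2
  # granularity), then by the smaller |g|, then by objective
  ord <- order(floor(abs(gs[cand] - init) + 1e-9), abs(gs[cand]),
               vals[cand])
  g_c <- gs[cand[ord[1]]]
  # quantized local refinement around the chosen candidate
  fine <- unique(quant(seq(g_c - coarse_step, g_c + coarse_step,
                           by = resolution)))
  fvals <- vapply(fine, obj, numeric(1))
  g_best <- fine[which.min(fvals)]
  structure(
    list(fitted_g = g_best,
         observed_sr_diff = observed_sr_diff,
         predicted_sr_diff = predict_sr_diff(g_best, params, spec,
                                             task_up, task_down),
         objective = min(fvals)),
    class = "adaptation_fit"
  )
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf(
    "<adaptation_fit> g = %.2f m/s^2 (observed dSR %.4f, predicted %.4f)\n",
    x$fitted_g, x$observed_sr_diff, x$predicted_sr_diff))
  invisible(x)
}

#' Internal-gravity time course across adaptation phases
#'
#' Applies [fit_internal_g()] to the observed symmetry-ratio difference
#' (down minus up) of each experimental phase in order (1g baseline, then
#' parabolas P1..P5), returning the fitted internal gravity sequence.
#'
#' The phases are fitted sequentially under a monotone-adaptation
#' constraint: each phase's search is bounded above by the previous
#' phase's fitted value and initialized there (the baseline phase is
#' initialized at the Earth-gravity prior 9.81). This makes the
#' otherwise two-branched inverse problem well-posed along the
#' adaptation trajectory; it assumes the internal estimate does not
#' increase during sustained exposure to weightlessness.
#'
#' @param phase_sr A data frame with columns `phase`, `sr_up`, `sr_down`
#'   (one row per phase) or `phase`, `sr_diff`.
#' @param params,spec,task_up,task_down,bounds,resolution Passed to
#'   [fit_internal_g()].
#' @param phases Expected phase order. Default `c("1g", "P1".."P5")`.
#' @param monotone Constrain fitted g to be non-increasing across phases?
#'   Default `TRUE`.
#' @return A tibble with columns `phase`, `observed_sr_diff`, `fitted_g`,
#'   `predicted_sr_diff`.
#' @export
adaptation_timecourse <- function(phase_sr, params,
                                  spec = cost_spec("smooth_effort"),
                                  task_up = movement_task(gamma = -pi / 2),
                                  task_down = movement_task(gamma = pi / 2),
                                  bounds = c(-2, 2) * 9.81,
                                  resolution = 0.05,
                                  phases = c("1g", paste0("P", 1:5)),
                                  monotone = TRUE) {
  stopifnot(is.data.frame(phase_sr), "phase" %in% names(phase_sr))
  if (!all(phases %in% phase_sr$phase)) {
    stop("missing phase(s): ",
         paste(setdiff(phases, phase_sr$phase), collapse = ", "))
  }
  init <- 9.81
  upper <- bounds[2]
  rows <- lapply(phases, function(ph) {
    row <- phase_sr[phase_sr$phase == ph, , drop = FALSE][1, ]
    d <- if ("sr_diff" %in% names(row)) row$sr_diff else
      row$sr_down - row$sr_up
    fit <- fit_internal_g(d, params, spec, task_up, task_down,
                          bounds = c(bounds[1], upper),
                          init = init, resolution = resolution)
    if (monotone) {
      upper <<- fit$fitted_g
    }
    init <<- fit$fitted_g
    tibble::tibble(phase = ph, observed_sr_diff = d,
                   fitted_g = fit$fitted_g,
                   predicted_sr_diff = fit$predicted_sr_diff)
  })
  dplyr::bind_rows(rows)
}

#' Per-phase mean symmetry ratios from a feature table
#'
#' Convenience aggregation for adaptation analyses: group-average SR per
#' phase and direction (up = negative `gamma`, down = positive), returned
#' in the shape [adaptation_timecourse()] expects.
#'
#' @param features Per-trial feature tibble (see [extract_features()])
#'   with columns `phase`, `gamma` (deg), `symmetry_ratio`.
#' @return A tibble with columns `phase`, `sr_up`, `sr_down`, `sr_diff`.
#' @export
phase_sr_table <- function(features) {
  stopifnot(all(c("phase", "gamma", "symmetry_ratio") %in%
                  names(features)))
  features |>
    dplyr::mutate(direction = ifelse(.data$gamma < 0, "up", "down")) |>
    dplyr::group_by(.data$phase, .data$direction) |>
    dplyr::summarise(sr = mean(.data$symmetry_ratio), .groups = "drop") |>
    tidyr_pivot() |>
    dplyr::mutate(sr_diff = .data$sr_down - .data$sr_up)
}

# minimal wide reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  up <- df[df$direction == "up", c("phase", "sr")]
  dn <- df[df$direction == "down", c("phase", "sr")]
  names(up)[2] <- "sr_up"
  names(dn)[2] <- "sr_down"
  dplyr::inner_join(up, dn, by = "phase")
}
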