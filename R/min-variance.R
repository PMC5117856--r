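# Open-loop minimum-variance planning with signal-dependent noise.
#
# The arm dynamics are linearized by freezing the gravity torque at its
# value in the initial posture, k = m g l cos(theta0) sin(gamma), and
# discretized with step dt. The state is x = (theta, theta_dot, tau) with
# control u = dtau/dt; control noise is multiplicative, w_t ~ N(0, s u_t^2)
# with noise scale s. The objective is the summed post-movement positional
# variance over a stabilization window of R steps after the movement,
# subject to the mean state reaching the static target at the end of the
# movement. Because the positional variance is a positively weighted sum of
# squared controls and the mean-target condition is linear in the controls,
# the problem is an equality-constrained diagonal quadratic program solved
# exactly via its KKT system.

variance_system <- function(task, params, spec) {
  dt <- spec$dt
  n <- task$duration / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("`spec$dt` must divide the movement duration evenly")
  }
  n <- as.integer(round(n))
  R <- if (is.null(spec$post_time)) n else as.integer(spec$post_time)
  if (R < 2) stop("post-movement stabilization window must be >= 2 steps")
  I <- params$inertia; B <- params$friction
  k <- params$arm_mass * params$gravity * params$lever_arm *
    cos(task$theta_start) * sin(task$gamma)
  A <- matrix(c(1, dt, 0,
                0, 1 - B * dt / I, dt / I,
                0, 0, 1), 3, 3, byrow = TRUE)
  Bv <- c(0, 0, dt)
  Cv <- c(0, k * dt / I, 0)
  # static postures require muscle torque opposing the (frozen) gravity
  # torque
  x0 <- c(task$theta_start, 0, -k)
  xT <- c(task$theta_end, 0, -k)
  # powers of A up to n + R
  Apow <- vector("list", n + R + 1)
  Apow[[1]] <- diag(3)
  for (j in seq_len(n + R)) Apow[[j + 1]] <- Apow[[j]] %*% A
  list(n = n, R = R, dt = dt, A = A, Bv = Bv, Cv = Cv, x0 = x0, xT = xT,
       Apow = Apow, k = k)
}

# Positional-impulse responses: g[t, i] = position component of
# A^(t - i) B, the effect of control u_{i-1} on the position at step t.
variance_weights <- function(sys, noise_scale) {
  n <- sys$n; R <- sys$R
  w <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in (n + 1):(n + R)) {
      acc <- acc + (sys$Apow[[t - i + 1]] %*% sys$Bv)[1]^2
    }
    w[i] <- noise_scale * acc
  }
  w
}

# Mean dynamics and recursive covariance propagation for a full control
# sequence (movement + hold). `Bmat` has one column per control channel.
propagate_moments <- function(A, Bmat, Cv, x0, U, noise_scale) {
  d <- length(x0)
  steps <- nrow(U)
  X <- matrix(0, steps + 1, d)
  S <- array(0, dim = c(d, d, steps + 1))
  X[1, ] <- x0
  for (t in seq_len(steps)) {
    X[t + 1, ] <- drop(A %*% X[t, ] + Bmat %*% U[t, ] + Cv)
    S[, , t + 1] <- A %*% S[, , t] %*% t(A)
    for (c in seq_len(ncol(Bmat))) {
      S[, , t + 1] <- S[, , t + 1] +
        noise_scale * U[t, c]^2 * tcrossprod(Bmat[, c])
    }
  }
  list(mean = X, cov = S, V = S[1, 1, ])
}

new_variance_state <- function(moments, controls, n, R, noise_scale) {
  V <- moments$V
  structure(
    list(state_mean = moments$mean, state_cov = moments$cov,
         controls = controls, V = V,
         terminal_variance_cost = sum(V[(n + 2):(n + R + 1)]),
         n_move = n, n_hold = R, noise_scale = noise_scale),
    class = "variance_state"
  )
}

#' @export
print.variance_state <- function(x, ...) {
  cat(sprintf(
    "<variance_state> %d movement + %d hold steps, terminal cost %.4g\n",
    x$n_move, x$n_hold, x$terminal_variance_cost))
  invisible(x)
}

#' Solve the minimum-variance trajectory (signal-dependent noise)
#'
#' Open-loop minimum-variance planning for the linearized single-joint arm:
#' the controls (torque rates) minimizing the summed positional variance of
#' the endpoint over the post-movement stabilization window, subject to the
#' mean trajectory reaching and holding the static target. Noise is
#' multiplicative (variance proportional to the squared control), so the
#' problem reduces to an exactly solvable equality-constrained quadratic
#' program.
#'
#' Under the frozen-gravity linearization the gravity level only shifts the
#' torque state; the optimal angle and velocity profiles are identical for
#' all movement directions, so the predicted symmetry ratio is
#' direction-invariant.
#'
#' @param task A [movement_task()] whose duration is a multiple of
#'   `spec$dt`.
#' @param params An [arm_parameters()] object.
#' @param spec A [cost_spec()] with `model = "variance"`.
#' @return A list with elements `trajectory` (`arm_trajectory` over the
#'   movement plus stabilization window) and `variance`
#'   (`variance_state`).
#' @export
#' @examples
#' p <- anthropometrics_from_body(70, 0.70)
#' sol <- solve_min_variance(movement_task(gamma = -pi / 2), p,
#'                           cost_spec("variance"))
#' trajectory_sr(sol$trajectory)
solve_min_variance <- function(task, params, spec = cost_spec("variance")) {
  stopifnot(inherits(task, "movement_task"),
            inherits(params, "arm_parameters"),
            inherits(spec, "cost_spec"))
  if (spec$model != "variance") stop("`spec$model` must be 'variance'")
  sys <- variance_system(task, params, spec)
  n <- sys$n; R <- sys$R

  w <- variance_weights(sys, spec$noise_scale)
  if (any(w <= 0)) stop("degenerate variance weights; increase post_time")
  # mean-target constraint M u = b
  M <- vapply(seq_len(n), function(i) {
    drop(sys$Apow[[n - i + 1]] %*% sys$Bv)
  }, numeric(3))
  drift <- Reduce(`+`, lapply(seq_len(n), function(i) {
    drop(sys$Apow[[n - i + 1]] %*% sys$Cv)
  }))
  b <- sys$xT - drop(sys$Apow[[n + 1]] %*% sys$x0) - drift
  # KKT solution of min u' W u  s.t.  M u = b
  WiMt <- t(M) / w                      # W^{-1} M'
  lambda <- solve(M %*% WiMt, b)
  u <- drop(WiMt %*% lambda)

  U <- matrix(c(u, rep(0, R)), ncol = 1)
  mom <- propagate_moments(sys$A, matrix(sys$Bv, ncol = 1), sys$Cv,
                           sys$x0, U, spec$noise_scale)
  vs <- new_variance_state(mom, U, n, R, spec$noise_scale)
  times <- seq(0, by = sys$dt, length.out = n + R + 1)
  accel <- (mom$mean[, 3] - params$friction * mom$mean[, 2] + sys$k) /
    params$inertia
  traj <- new_trajectory(
    times = times, angle = mom$mean[, 1], velocity = mom$mean[, 2],
    acceleration = accel, torque = mom$mean[, 3],
    model = "variance", cost_value = vs$terminal_variance_cost,
    task = task
  )
  list(trajectory = traj, variance = vs)
}

# ---------------------------------------------------------------------------
# Muscle-dynamics variant: state (theta, theta_dot, a_ag, a_ant), controls
# (u_ag, u_ant) in [0,1]^2, first-order muscle filters with time constant
# muscle_tau, net torque muscle_gain * (a_ag - a_ant).

muscle_system <- function(task, params, spec) {
  dt <- spec$dt
  n <- task$duration / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("`spec$dt` must divide the movement duration evenly")
  }
  n <- as.integer(round(n))
  R <- if (is.null(spec$post_time)) n else as.integer(spec$post_time)
  if (R < 2) stop("post-movement stabilization window must be >= 2 steps")
  I <- params$inertia; B <- params$friction
  rho <- spec$muscle_gain; tau_m <- spec$muscle_tau
  k <- params$arm_mass * params$gravity * params$lever_arm *
    cos(task$theta_start) * sin(task$gamma)
  A <- diag(4)
  A[1, 2] <- dt
  A[2, 2] <- 1 - B * dt / I
  A[2, 3] <- rho * dt / I
  A[2, 4] <- -rho * dt / I
  A[3, 3] <- 1 - dt / tau_m
  A[4, 4] <- 1 - dt / tau_m
  Bmat <- cbind(c(0, 0, dt / tau_m, 0), c(0, 0, 0, dt / tau_m))
  Cv <- c(0, k * dt / I, 0, 0)
  # one-sided static activations holding the arm against gravity
  hold_torque <- -k
  a_hold <- if (hold_torque >= 0) c(hold_torque / rho, 0) else
    c(0, -hold_torque / rho)
  if (max(a_hold) > 1) {
    stop(sprintf(
      "`muscle_gain` = %.3g N m is too small to hold the arm against the gravity torque (%.3g N m)",
      rho, abs(hold_torque)))
  }
  x0 <- c(task$theta_start, 0, a_hold)
  xT <- c(task$theta_end, 0, a_hold)
  Apow <- vector("list", n + R + 1)
  Apow[[1]] <- diag(4)
  for (j in seq_len(n + R)) Apow[[j + 1]] <- Apow[[j]] %*% A
  list(n = n, R = R, dt = dt, A = A, Bmat = Bmat, Cv = Cv, x0 = x0,
       xT = xT, Apow = Apow, k = k, a_hold = a_hold, rho = rho,
       tau_m = tau_m)
}

#' Solve the minimum-variance trajectory with muscle dynamics
#'
#' As [solve_min_variance()], but with agonist and antagonist muscles
#' modeled as first-order low-pass filters (time constant
#' `spec$muscle_tau`), net torque `spec$muscle_gain * (a_ag - a_ant)`, and
#' motoneuron inputs bounded in `[0, 1]` (hence non-negative activations
#' and muscle torques). The mean trajectory is constrained to reach the
#' target at the end of the movement and to keep zero mean velocity at
#' every step of the stabilization window; controls during the window are
#' decision variables (activations cannot be driven to an exact value and
#' released, so the hold must be enforced on position and velocity, not on
#' the muscle states). The resulting convex bound-constrained quadratic
#' program is solved exactly with the Goldfarb-Idnani dual active-set
#' method ([quadprog::solve.QP()]).
#'
#' @inheritParams solve_min_variance
#' @param spec A [cost_spec()] with `model = "variance_muscle"`.
#' @return A list with elements `trajectory`, `variance`, and
#'   `activations` (matrix with columns `a_ag`, `a_ant` per step).
#' @export
solve_min_variance_muscle <- function(task, params,
                                      spec = cost_spec("variance_muscle")) {
  stopifnot(inherits(task, "movement_task"),
            inherits(params, "arm_parameters"),
            inherits(spec, "cost_spec"))
  if (spec$model != "variance_muscle") {
    stop("`spec$model` must be 'variance_muscle'")
  }
  sys <- muscle_system(task, params, spec)
  n <- sys$n; R <- sys$R
  nu <- n + R          # controlled steps per channel
  N <- 2 * nu          # stacked (u_ag, u_ant)

  # impulse responses: effect of the control applied at step i on state
  # component r at step s is [A^(s-i) B_c]_r (zero for s < i)
  imp <- function(ch, r, s) {
    vapply(seq_len(nu), function(i) {
      if (s < i) 0 else (sys$Apow[[s - i + 1]] %*% sys$Bmat[, ch])[r]
    }, numeric(1))
  }
  # positional-variance weights over the stabilization window
  wvec <- numeric(N)
  for (ch in 1:2) {
    for (s in (n + 1):(n + R)) {
      g1 <- imp(ch, 1, s)
      wvec[(ch - 1) * nu + seq_len(nu)] <-
        wvec[(ch - 1) * nu + seq_len(nu)] + spec$noise_scale * g1^2
    }
  }

  # mean constraints: position at step n; velocity zero at steps n..n+R
  free_mean <- function(s) {
    drift <- if (s >= 1) {
      Reduce(`+`, lapply(seq_len(s), function(i) {
        drop(sys$Apow[[s - i + 1]] %*% sys$Cv)
      }))
    } else rep(0, 4)
    drop(sys$Apow[[s + 1]] %*% sys$x0) + drift
  }
  eq_rows <- list(c(imp(1, 1, n), imp(2, 1, n)))
  eq_rhs <- c(task$theta_end - free_mean(n)[1])
  for (s in n:(n + R)) {
    eq_rows <- c(eq_rows, list(c(imp(1, 2, s), imp(2, 2, s))))
    eq_rhs <- c(eq_rhs, -free_mean(s)[2])
  }
  Meq <- do.call(rbind, eq_rows)
  row_scale <- sqrt(rowSums(Meq^2))
  row_scale[row_scale == 0] <- 1
  Meq <- Meq / row_scale
  beq <- eq_rhs / row_scale

  Dmat <- diag(2 * wvec + 1e-8 * max(wvec))
  Amat <- t(rbind(Meq, diag(N), -diag(N)))
  bvec <- c(beq, rep(0, N), rep(-1, N))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, rep(0, N), Amat, bvec, meq = nrow(Meq)),
    error = function(e) {
      stop(sprintf(
        "muscle variance QP infeasible or failed (%s); check that `muscle_gain` can move and hold the arm",
        conditionMessage(e)))
    })
  v <- pmin(pmax(sol$solution, 0), 1)
  resid <- drop(Meq %*% v) - beq
  if (max(abs(resid)) > 1e-6) {
    stop(sprintf(
      "muscle variance solver failed to meet the mean-hold constraints (max residual %.3g)",
      max(abs(resid))))
  }

  U <- matrix(v, ncol = 2)
  mom <- propagate_moments(sys$A, sys$Bmat, sys$Cv, sys$x0, U,
                           spec$noise_scale)
  vs <- new_variance_state(mom, U, n, R, spec$noise_scale)
  times <- seq(0, by = sys$dt, length.out = n + R + 1)
  torque <- sys$rho * (mom$mean[, 3] - mom$mean[, 4])
  accel <- (torque - params$friction * mom$mean[, 2] + sys$k) /
    params$inertia
  traj <- new_trajectory(
    times = times, angle = mom$mean[, 1], velocity = mom$mean[, 2],
    acceleration = accel, torque = torque,
    model = "variance_muscle", cost_value = vs$terminal_variance_cost,
    task = task
  )
  list(trajectory = traj, variance = vs,
       activations = mom$mean[, 3:4, drop = FALSE])
}
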