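# Direct trajectory optimization by a global polynomial (Ritz) method.
#
# For the Smooth-Effort and torque-change costs the control is the torque
# rate, and the dynamics define torque explicitly from the angle and its
# derivatives, so the optimal-control problem reduces to an unconstrained
# minimization over smooth angle trajectories satisfying the rest-to-rest
# boundary conditions. The angle is parameterized as the minimum-jerk
# quintic plus a polynomial perturbation
#   theta(s) = theta_mj(s) + sum_k c_k * E(s) * P_k(2s - 1),  s = t/T,
# with envelope E(s) = s^3 (1-s)^3 and shifted Legendre polynomials P_k.
# The envelope forces the perturbation and its first two derivatives to
# vanish at both ends, so every candidate satisfies theta(0) = theta0,
# theta(T) = thetaf, zero boundary velocity and zero boundary acceleration
# (hence static boundary torque) exactly, and the dynamics hold exactly at
# every node. Cost integrals are evaluated by Gauss-Legendre quadrature and
# minimized by BFGS with analytic gradients.

# Legendre polynomials P_0..P_{K-1} and first three derivatives at x in
# [-1, 1], by the differentiated three-term recurrence.
legendre_derivs <- function(K, x) {
  n <- length(x)
  P0 <- matrix(0, n, K); P1 <- P0; P2 <- P0; P3 <- P0
  P0[, 1] <- 1
  if (K >= 2) {
    P0[, 2] <- x
    P1[, 2] <- 1
  }
  if (K >= 3) {
    for (k in 1:(K - 2)) {
      a <- (2 * k + 1) / (k + 1); b <- k / (k + 1)
      j <- k + 2  # column of P_{k+1}
      P0[, j] <- a * x * P0[, j - 1] - b * P0[, j - 2]
      P1[, j] <- a * (P0[, j - 1] + x * P1[, j - 1]) - b * P1[, j - 2]
      P2[, j] <- a * (2 * P1[, j - 1] + x * P2[, j - 1]) - b * P2[, j - 2]
      P3[, j] <- a * (3 * P2[, j - 1] + x * P3[, j - 1]) - b * P3[, j - 2]
    }
  }
  list(P0 = P0, P1 = P1, P2 = P2, P3 = P3)
}

# Basis matrices Phi0..Phi3 (d^r/ds^r of the basis) at normalized times s.
# `scales` rescales columns for optimizer conditioning; it must be shared
# between the quadrature grid and the output grid.
ritz_basis <- function(n_basis, s, scales = NULL) {
  E0 <- s^3 - 3 * s^4 + 3 * s^5 - s^6
  E1 <- 3 * s^2 - 12 * s^3 + 15 * s^4 - 6 * s^5
  E2 <- 6 * s - 36 * s^2 + 60 * s^3 - 30 * s^4
  E3 <- 6 - 72 * s + 180 * s^2 - 120 * s^3
  L <- legendre_derivs(n_basis, 2 * s - 1)
  # chain rule: each d/ds of P(2s - 1) brings a factor 2
  Phi0 <- E0 * L$P0
  Phi1 <- E1 * L$P0 + 2 * E0 * L$P1
  Phi2 <- E2 * L$P0 + 4 * E1 * L$P1 + 4 * E0 * L$P2
  Phi3 <- E3 * L$P0 + 6 * E2 * L$P1 + 12 * E1 * L$P2 + 8 * E0 * L$P3
  if (is.null(scales)) {
    scales <- apply(abs(Phi0), 2, max)
    scales[scales == 0] <- 1
  }
  list(Phi0 = sweep(Phi0, 2, scales, "/"),
       Phi1 = sweep(Phi1, 2, scales, "/"),
       Phi2 = sweep(Phi2, 2, scales, "/"),
       Phi3 = sweep(Phi3, 2, scales, "/"),
       scales = scales)
}

# Minimum-jerk quintic and derivatives in normalized time s.
minjerk_shape <- function(s) {
  list(q0 = 10 * s^3 - 15 * s^4 + 6 * s^5,
       q1 = 30 * s^2 - 60 * s^3 + 30 * s^4,
       q2 = 60 * s - 180 * s^2 + 120 * s^3,
       q3 = 60 - 360 * s + 360 * s^2)
}

# Evaluate angle and time derivatives on a grid given coefficients.
ritz_eval <- function(coef, basis, mj, task) {
  D <- task$theta_end - task$theta_start
  T <- task$duration
  list(
    theta = task$theta_start + D * mj$q0 + drop(basis$Phi0 %*% coef),
    omega = (D * mj$q1 + drop(basis$Phi1 %*% coef)) / T,
    accel = (D * mj$q2 + drop(basis$Phi2 %*% coef)) / T^2,
    jerk  = (D * mj$q3 + drop(basis$Phi3 %*% coef)) / T^3
  )
}

# Net muscle torque from the equation of motion:
# tau = I * accel + B * omega - GT(theta, gamma).
# Gravity torque GT acts toward the target when positive, so it is
# subtracted from the muscle requirement.
torque_from_kinematics <- function(theta, omega, accel, task, params) {
  params$inertia * accel + params$friction * omega -
    gravity_torque(theta, task$gamma, params)
}

# Objective/gradient closures ------------------------------------------------

make_smooth_effort_objective <- function(task, params, basis, mj, wts,
                                         alpha, eps) {
  I <- params$inertia; B <- params$friction; T <- task$duration
  mgl_sg <- params$arm_mass * params$gravity * params$lever_arm *
    sin(task$gamma)
  fn <- function(coef) {
    k <- ritz_eval(coef, basis, mj, task)
    tau <- I * k$accel + B * k$omega - mgl_sg * cos(k$theta)
    P <- tau * k$omega
    sum(wts * (sqrt(P^2 + eps^2) + alpha * k$jerk^2))
  }
  gr <- function(coef) {
    k <- ritz_eval(coef, basis, mj, task)
    tau <- I * k$accel + B * k$omega - mgl_sg * cos(k$theta)
    P <- tau * k$omega
    sP <- P / sqrt(P^2 + eps^2)
    # d tau / d coef and d omega / d coef (node x coef matrices)
    dtau <- I * basis$Phi2 / T^2 + B * basis$Phi1 / T +
      mgl_sg * sin(k$theta) * basis$Phi0
    gr_eff <- crossprod(dtau, wts * sP * k$omega) +
      crossprod(basis$Phi1 / T, wts * sP * tau)
    gr_sm <- crossprod(basis$Phi3 / T^3, wts * 2 * alpha * k$jerk)
    drop(gr_eff + gr_sm)
  }
  list(fn = fn, gr = gr)
}

make_torque_change_objective <- function(task, params, basis, mj, wts) {
  I <- params$inertia; B <- params$friction; T <- task$duration
  mgl_sg <- params$arm_mass * params$gravity * params$lever_arm *
    sin(task$gamma)
  fn <- function(coef) {
    k <- ritz_eval(coef, basis, mj, task)
    u <- I * k$jerk + B * k$accel + mgl_sg * sin(k$theta) * k$omega
    sum(wts * u^2)
  }
  gr <- function(coef) {
    k <- ritz_eval(coef, basis, mj, task)
    u <- I * k$jerk + B * k$accel + mgl_sg * sin(k$theta) * k$omega
    du <- I * basis$Phi3 / T^3 + B * basis$Phi2 / T^2 +
      mgl_sg * (cos(k$theta) * k$omega * basis$Phi0 +
                  sin(k$theta) * basis$Phi1 / T)
    drop(crossprod(du, wts * 2 * u))
  }
  list(fn = fn, gr = gr)
}

# Core driver ---------------------------------------------------------------

solve_ritz <- function(task, params, model, spec, init = "minjerk") {
  n_basis <- spec$n_basis
  gl <- pracma::gaussLegendre(spec$n_quad, 0, 1)
  wts <- gl$w * task$duration  # time-integral weights
  basis_q <- ritz_basis(n_basis, gl$x)
  mj_q <- minjerk_shape(gl$x)

  coef <- rep(0, n_basis)
  if (identical(init, "cosine")) {
    # project the cosine-ramp profile onto the basis as an alternative,
    # clearly different starting point (initialization-robustness checks)
    q_cos <- (1 - cos(pi * gl$x)) / 2
    D <- task$theta_end - task$theta_start
    resid <- D * (q_cos - mj_q$q0)
    coef <- qr.solve(basis_q$Phi0, resid)
  } else if (is.numeric(init)) {
    stopifnot(length(init) == n_basis)
    coef <- init
  }

  if (model == "smooth_effort") {
    eps_target <- spec$effort_smoothing
    eps_seq <- unique(c(1e-2, 1e-4, eps_target))
    eps_seq <- sort(eps_seq[eps_seq >= eps_target], decreasing = TRUE)
    value <- NA_real_
    for (eps in eps_seq) {
      obj <- make_smooth_effort_objective(task, params, basis_q, mj_q,
                                          wts, spec$alpha, eps)
      fit <- stats::optim(coef, obj$fn, obj$gr, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14))
      coef <- fit$par
      value <- fit$value
    }
  } else if (model == "torque_change") {
    obj <- make_torque_change_objective(task, params, basis_q, mj_q, wts)
    fit <- stats::optim(coef, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    coef <- fit$par
    value <- fit$value
  } else {
    stop("unknown Ritz model: ", model)
  }
  if (!all(is.finite(coef))) {
    stop(sprintf("trajectory optimization for model '%s' diverged", model))
  }

  s_out <- seq(0, 1, length.out = spec$n_out)
  basis_o <- ritz_basis(n_basis, s_out, scales = basis_q$scales)
  k <- ritz_eval(coef, basis_o, minjerk_shape(s_out), task)
  tau <- torque_from_kinematics(k$theta, k$omega, k$accel, task, params)
  tr <- new_trajectory(
    times = s_out * task$duration, angle = k$theta, velocity = k$omega,
    acceleration = k$accel, torque = tau, jerk = k$jerk,
    model = model, cost_value = value, task = task
  )
  tr$coef <- coef
  tr
}
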