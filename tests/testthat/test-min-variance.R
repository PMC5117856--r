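test_that("covariance is zero whenever controls are zero", {
  p <- nominal_params()
  spec <- cost_spec("variance")
  sys <- armplan:::variance_system(task_up(), p, spec)
  U <- matrix(0, sys$n + sys$R, 1)
  mom <- armplan:::propagate_moments(sys$A, matrix(sys$Bv, ncol = 1),
                                     sys$Cv, sys$x0, U, spec$noise_scale)
  expect_equal(max(abs(mom$cov)), 0)
  expect_equal(mom$V, rep(0, sys$n + sys$R + 1))
})

test_that("recursive covariance matches the explicit impulse-response sum", {
  # oracle: cov[x_t] = s * sum_i (A^(t-1-i) B)(A^(t-1-i) B)' u_i^2,
  # evaluated directly, against the recursive propagation used internally
  p <- nominal_params()
  spec <- cost_spec("variance")
  sol <- solve_min_variance(task_down(), p, spec)
  sys <- armplan:::variance_system(task_down(), p, spec)
  u <- sol$variance$controls[, 1]
  for (t in c(5L, 20L, sys$n, sys$n + 10L)) {
    S <- matrix(0, 3, 3)
    for (i in seq_len(t)) {
      Ab <- sys$Apow[[t - i + 1]] %*% sys$Bv
      S <- S + spec$noise_scale * u[i]^2 * tcrossprod(Ab)
    }
    expect_equal(sol$variance$state_cov[, , t + 1], S, tolerance = 1e-10)
  }
  # and the reported cost is the summed post-movement positional variance
  expect_equal(sol$variance$terminal_variance_cost,
               sum(sol$variance$V[(sys$n + 2):(sys$n + sys$R + 1)]))
})

test_that("positional variance is non-decreasing while controls are active", {
  p <- nominal_params()
  sol <- solve_min_variance(task_up(), p)
  n <- sol$variance$n_move
  V <- sol$variance$V
  expect_true(all(diff(V[1:(n + 1)]) >= -1e-15))
  expect_true(all(V >= 0))
})

test_that("minimum-variance mean reaches and holds the static target", {
  p <- nominal_params()
  sol <- solve_min_variance(task_down(), p)
  n <- sol$variance$n_move
  X <- sol$variance$state_mean
  expect_equal(X[n + 1, 1], pi / 4, tolerance = 1e-9)
  expect_equal(X[n + 1, 2], 0, tolerance = 1e-9)
  # hold window: position stays at the target with zero velocity
  expect_lt(max(abs(X[(n + 1):nrow(X), 1] - pi / 4)), 1e-9)
  expect_lt(max(abs(X[(n + 1):nrow(X), 2])), 1e-9)
})

test_that("minimum-variance SR is identical across movement directions", {
  # under the frozen-gravity linearization the gravity level only shifts
  # the torque state, so the angle profile is direction-invariant
  p <- nominal_params()
  srs <- vapply(direction_set(5), function(g) {
    sr_of(solve_min_variance(movement_task(gamma = g), p)$trajectory)
  }, numeric(1))
  expect_lt(max(srs) - min(srs), 1e-9)
})

test_that("dt must divide the movement duration", {
  p <- nominal_params()
  bad <- movement_task(duration = 0.403)
  expect_error(solve_min_variance(bad, p), "divide")
})

test_that("muscle-model activations and inputs respect the [0,1] bounds", {
  p <- nominal_params()
  sol <- solve_min_variance_muscle(task_up(), p)
  expect_true(all(sol$variance$controls >= -1e-9))
  expect_true(all(sol$variance$controls <= 1 + 1e-9))
  expect_true(all(sol$activations >= -1e-6))
  expect_true(all(sol$activations <= 1 + 1e-6))
})

test_that("muscle-model mean trajectory satisfies the muscle dynamics", {
  # finite-difference residual of the equation of motion with net torque
  # rho (a_ag - a_ant) and of the first-order activation filters
  p <- nominal_params()
  spec <- cost_spec("variance_muscle")
  sol <- solve_min_variance_muscle(task_down(), p, spec)
  sys <- armplan:::muscle_system(task_down(), p, spec)
  X <- sol$variance$state_mean
  U <- sol$variance$controls
  steps <- nrow(U)
  for (t in seq_len(steps)) {
    xn <- drop(sys$A %*% X[t, ] + sys$Bmat %*% U[t, ] + sys$Cv)
    expect_equal(X[t + 1, ], xn, tolerance = 1e-9)
  }
  # velocity update embeds rho (a_ag - a_ant) - B thdot + k
  t <- 10L
  acc <- (spec$muscle_gain * (X[t, 3] - X[t, 4]) -
            p$friction * X[t, 2] + sys$k) / p$inertia
  expect_equal((X[t + 1, 2] - X[t, 2]) / sys$dt, acc, tolerance = 1e-9)
})

test_that("muscle-model SR is near-constant across directions and robust to the gain", {
  p <- nominal_params()
  srs <- vapply(direction_set(5), function(g) {
    sr_of(solve_min_variance_muscle(movement_task(gamma = g),
                                    p)$trajectory)
  }, numeric(1))
  expect_lt(max(srs) - min(srs), 0.01)
  # sensitivity: +50% gain and +-50% muscle time constant keep the spread
  # an order of magnitude below the Smooth-Effort direction modulation
  # (~0.14). Halving the gain is excluded: 30 N m barely covers the
  # ~32 N m peak torque demand, so the activation bounds bind and
  # invariance genuinely degrades at that feasibility edge.
  for (s2 in list(cost_spec("variance_muscle", muscle_gain = 90),
                  cost_spec("variance_muscle", muscle_tau = 0.025),
                  cost_spec("variance_muscle", muscle_tau = 0.075))) {
    r2 <- vapply(c(-pi / 2, 0, pi / 2), function(g) {
      sr_of(solve_min_variance_muscle(movement_task(gamma = g),
                                      p, s2)$trajectory)
    }, numeric(1))
    expect_lt(max(r2) - min(r2), 0.03)
  }
})

test_that("an implausibly weak muscle gain is rejected", {
  p <- nominal_params()
  weak <- cost_spec("variance_muscle", muscle_gain = 5)
  expect_error(solve_min_variance_muscle(task_up(), p, weak),
               "muscle_gain|infeasible")
})
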