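test_that("minimum-jerk solution matches the quintic closed form", {
  task <- movement_task()
  tr <- solve_min_jerk(task)
  # peak speed (15/8) * amplitude / T at t = T/2
  expect_equal(max(tr$velocity), 15 / 8 * task$amplitude / task$duration,
               tolerance = 1e-9)
  expect_equal(tr$times[which.max(tr$velocity)], task$duration / 2,
               tolerance = 1e-9)
  # SR exactly 0.5 for any task
  expect_equal(sr_of(tr), 0.5, tolerance = 1e-6)
  expect_equal(sr_of(solve_min_jerk(movement_task(gamma = pi / 3,
                                                  duration = 0.7))),
               0.5, tolerance = 1e-6)
  # reversing start and end mirrors the trajectory
  rev_task <- movement_task(theta_start = pi / 4, theta_end = 0)
  tr_rev <- solve_min_jerk(rev_task)
  expect_equal(tr_rev$angle, rev(tr$angle), tolerance = 1e-12)
})

test_that("all solved trajectories satisfy the rest-to-rest boundary contract", {
  p <- nominal_params()
  for (tr in list(
    cached_smooth_effort(task_up(), p),
    cached_smooth_effort(task_down(), p),
    solve_torque_change(movement_task(gamma = pi / 6), p),
    solve_min_jerk(task_up())
  )) {
    n <- length(tr$times)
    expect_lt(abs(tr$angle[1] - 0), 1e-4)
    expect_lt(abs(tr$angle[n] - pi / 4), 1e-4)
    expect_lt(abs(tr$velocity[1]), 1e-3)
    expect_lt(abs(tr$velocity[n]), 1e-3)
  }
})

test_that("solved trajectories satisfy the arm dynamics at every node", {
  p <- nominal_params()
  tr <- cached_smooth_effort(task_down(), p)
  tau <- p$inertia * tr$acceleration + p$friction * tr$velocity -
    gravity_torque(tr$angle, tr$task$gamma, p)
  expect_equal(tr$torque, tau, tolerance = 1e-10)
  # boundary torque is the static gravity-opposing torque
  expect_equal(tr$torque[1], -gravity_torque(0, tr$task$gamma, p),
               tolerance = 1e-6)
})

test_that("Smooth-Effort predicts earlier peaks upward than downward at 1g", {
  p <- nominal_params()
  sr_up <- sr_of(cached_smooth_effort(task_up(), p))
  sr_dn <- sr_of(cached_smooth_effort(task_down(), p))
  expect_lt(sr_up, sr_dn)
  expect_lt(sr_up, 0.5)
  expect_gt(sr_dn, 0.5)
})

test_that("Smooth-Effort asymmetry vanishes at zero gravity", {
  p0 <- nominal_params(gravity = 0)
  sr_up <- sr_of(cached_smooth_effort(task_up(), p0))
  sr_dn <- sr_of(cached_smooth_effort(task_down(), p0))
  expect_lt(abs(sr_up - sr_dn), 0.005)
})

test_that("Smooth-Effort SR saturates at 0.5 as the jerk weight grows", {
  p <- nominal_params()
  alphas <- c(7e-5, 7e-3, 7e-1)
  srs <- vapply(alphas, function(a) {
    sr_of(solve_smooth_effort(task_up(), p,
                              cost_spec("smooth_effort", alpha = a)))
  }, numeric(1))
  # monotone approach to 0.5 from below for the upward task
  expect_true(all(diff(abs(srs - 0.5)) < 0))
  expect_lt(abs(srs[length(srs)] - 0.5), 0.005)
})

test_that("halving the effort smoothing width leaves SR unchanged", {
  p <- nominal_params()
  s1 <- cost_spec("smooth_effort", effort_smoothing = 1e-6)
  s2 <- cost_spec("smooth_effort", effort_smoothing = 5e-7)
  sr1 <- sr_of(solve_smooth_effort(task_down(), p, s1))
  sr2 <- sr_of(solve_smooth_effort(task_down(), p, s2))
  expect_lt(abs(sr1 - sr2), 0.001)
})

test_that("Smooth-Effort solutions are initialization-independent", {
  p <- nominal_params()
  task <- movement_task(gamma = -pi / 3)
  a <- solve_smooth_effort(task, p, init = "minjerk")
  b <- solve_smooth_effort(task, p, init = "cosine")
  expect_lt(abs(a$cost_value - b$cost_value) / a$cost_value, 1e-4)
  expect_lt(abs(sr_of(a) - sr_of(b)), 1e-3)
})

test_that("grid refinement changes cost by < 1% and SR by < 0.005", {
  p <- nominal_params()
  for (model in c("smooth_effort", "torque_change")) {
    coarse <- cost_spec(model)
    fine <- cost_spec(model, n_basis = 2 * coarse$n_basis,
                      n_quad = 2 * coarse$n_quad)
    solver <- if (model == "smooth_effort") solve_smooth_effort else
      solve_torque_change
    a <- solver(task_up(), p, coarse)
    b <- solver(task_up(), p, fine)
    expect_lt(abs(a$cost_value - b$cost_value) / abs(b$cost_value), 0.01)
    expect_lt(abs(sr_of(a) - sr_of(b)), 0.005)
  }
})

test_that("torque change reduces to minimum jerk without gravity and friction", {
  p00 <- arm_parameters(3.5, 0.371, 0.7135, friction = 0, gravity = 0)
  tr <- solve_torque_change(task_up(), p00)
  mj <- solve_min_jerk(task_up())
  expect_lt(max(abs(tr$angle - mj$angle)), 1e-3)
  expect_equal(sr_of(tr), 0.5, tolerance = 1e-3)
})

test_that("torque-change optimum costs no more than the min-jerk trajectory", {
  p <- nominal_params()
  task <- task_down()
  opt <- solve_torque_change(task, p)
  mj <- solve_min_jerk_torque(task, p)
  mj$jerk <- solve_min_jerk(task)$jerk
  expect_lte(torque_change_cost(opt, p),
             torque_change_cost(mj, p) * (1 + 1e-6))
})

test_that("torque-change SR is direction-invariant across the 17 directions", {
  p <- nominal_params()
  srs <- vapply(direction_set(17), function(g) {
    sr_of(solve_torque_change(movement_task(gamma = g), p))
  }, numeric(1))
  expect_lt(max(srs) - min(srs), 0.01)
})
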