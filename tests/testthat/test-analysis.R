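test_that("sigmoid fit recovers exact-model parameters", {
  x <- seq(-90, 90, length.out = 17)
  y <- 0.42 + 0.12 / (1 + exp(-(x - 5) / 25))
  f <- fit_sigmoid(x, y)
  expect_lt(f$rmse, 1e-8)
  expect_equal(f$p1, 0.42, tolerance = 1e-4)
  expect_equal(f$p2, 0.12, tolerance = 1e-4)
  expect_equal(f$p3, 5, tolerance = 1e-2)
  expect_equal(f$p4, 25, tolerance = 1e-2)
})

test_that("sigmoid fit accepts a constant plateau as the degenerate case", {
  x <- seq(-90, 90, length.out = 9)
  f <- fit_sigmoid(x, rep(0.5, 9))
  expect_equal(f$p2, 0, tolerance = 1e-10)
  expect_lt(f$rmse, 1e-10)
  expect_true(f$p4 != 0)
})

test_that("sigmoid RMSE at known noise level falls in the expected band", {
  # frozen from the generating model: sd 0.01 noise on 17 points leaves
  # an RMSE near 0.01 * sqrt((n - 4)/n); the seed-1 draw gives 0.00884
  set.seed(1)
  x <- seq(-90, 90, length.out = 17)
  y <- 0.42 + 0.12 / (1 + exp(-(x - 5) / 25)) + rnorm(17, 0, 0.01)
  f <- fit_sigmoid(x, y)
  expect_equal(f$rmse, 0.008844478, tolerance = 1e-6)
  expect_gt(f$rmse, 0.005)
  expect_lt(f$rmse, 0.02)
})

test_that("fit_sigmoid validates its inputs", {
  expect_error(fit_sigmoid(c(1, 2, 3), c(1, 2, 3)), ">= 5")
  expect_error(fit_sigmoid(c(3, 2, 1, 4, 5), rnorm(5)), "increasing")
})

test_that("correlate matches the textbook formula and validates input", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 4, 6, 9)
  # oracle: direct product-moment formula
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(correlate(x, y), r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  expect_error(correlate(x, rep(1, 5)), "constant")
  expect_error(correlate(x, y[1:3]), "equal length")
  # symmetry and affine invariance
  expect_equal(correlate(x, y), correlate(y, x))
  expect_equal(correlate(3 * x - 2, y), correlate(x, y))
})

test_that("the predicted SR curve is flat at zero gravity and tuned at 1g", {
  p0 <- nominal_params(gravity = 0)
  dirs <- direction_set(5)
  flat <- predict_sr_curve(p0, directions = dirs)
  expect_lt(max(flat$sr) - min(flat$sr), 0.005)
  # symmetric in +-gamma without gravity
  expect_equal(flat$sr[1], flat$sr[5], tolerance = 1e-4)
  p <- nominal_params()
  tuned <- predict_sr_curve(p, directions = dirs)
  # strongly tuned: gravity-assisted directions have late peaks,
  # gravity-opposed directions early peaks, and SR tracks WGT
  expect_gt(max(tuned$sr) - min(tuned$sr), 0.05)
  expect_gt(tuned$sr[which.max(tuned$wgt)],
            tuned$sr[which.min(tuned$wgt)] + 0.05)
  expect_gt(correlate(tuned$sr, tuned$wgt), 0.8)
})

test_that("jerk-model SR curve is exactly flat at 0.5", {
  p <- nominal_params()
  curve <- predict_sr_curve(p, cost_spec("jerk"), direction_set(5))
  expect_equal(curve$sr, rep(0.5, 5), tolerance = 1e-5)
})

test_that("internal-gravity fit is self-consistent at Earth gravity", {
  p <- nominal_params()
  d <- predict_sr_diff(9.81, p, cost_spec("smooth_effort"),
                       task_up(), task_down())
  f <- fit_internal_g(d, p)
  expect_lt(abs(f$fitted_g - 9.81), 0.5)
  expect_equal(f$predicted_sr_diff, d, tolerance = 0.005)
})

test_that("zero observed asymmetry maps to zero internal gravity", {
  p <- nominal_params()
  f <- fit_internal_g(0, p)
  expect_lt(abs(f$fitted_g), 0.5)
})

test_that("sequential fitting recovers a decreasing gravity sweep", {
  p <- nominal_params()
  sweep <- c(9.81, 7.5, 5, 2.5, 0)
  obs <- vapply(sweep, function(g) {
    predict_sr_diff(g, p, cost_spec("smooth_effort"),
                    task_up(), task_down())
  }, numeric(1))
  tc <- adaptation_timecourse(
    data.frame(phase = c("1g", "P1", "P2", "P3", "P4"), sr_diff = obs),
    p, phases = c("1g", "P1", "P2", "P3", "P4"))
  expect_true(all(diff(tc$fitted_g) <= 1e-9))
  expect_lt(max(abs(tc$fitted_g - sweep)), 0.5)
})

test_that("identical up/down SR in every phase yields fitted g near 0", {
  p <- nominal_params()
  tab <- data.frame(phase = c("1g", paste0("P", 1:5)),
                    sr_up = 0.45, sr_down = 0.45)
  tc <- adaptation_timecourse(tab, p)
  expect_true(all(abs(tc$fitted_g) < 0.5))
})

test_that("adaptation timecourse requires every phase", {
  p <- nominal_params()
  expect_error(
    adaptation_timecourse(data.frame(phase = "1g", sr_diff = 0.1), p),
    "missing phase")
})

test_that("the model SR tuning curve is sigmoid with small residual", {
  p <- nominal_params()
  curve <- predict_sr_curve(p, directions = direction_set(17))
  fit <- fit_sigmoid(curve$gamma, curve$sr)
  expect_lt(fit$rmse, 0.1 * diff(range(curve$sr)))
})
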