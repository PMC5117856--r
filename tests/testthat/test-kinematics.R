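test_that("the low-pass filter preserves DC and slow components, kills fast ones", {
  fs <- 120
  t <- (0:599) / fs
  # constant series passes unchanged
  expect_equal(lowpass(rep(2.5, 600), fs), rep(2.5, 600),
               tolerance = 1e-9)
  # analytic oracle: zero-phase 5th-order Butterworth magnitude at
  # frequency f is (1 + (f/fc)^10)^-1 (forward-backward squares |H|)
  gain <- function(f, fc = 10, ord = 5) 1 / (1 + (f / fc)^(2 * ord))
  interior <- 150:450
  for (f in c(1, 40)) {
    x <- sin(2 * pi * f * t)
    y <- lowpass(x, fs)
    measured <- max(abs(y[interior])) / max(abs(x[interior]))
    if (f == 1) {
      expect_gt(measured, 0.99)            # < 1% attenuation
      expect_equal(measured, gain(1), tolerance = 0.005)
    } else {
      expect_lt(measured, 0.01)            # > 99% attenuation
    }
  }
  expect_error(lowpass(1:5, fs), "short")
})

test_that("tangential speed recovers analytic speeds and is frame-invariant", {
  fs <- 120
  t <- (0:479) / fs
  omega <- 2; radius <- 0.7
  circ <- cbind(radius * cos(omega * t), radius * sin(omega * t), 0 * t)
  rec <- marker_recording(list(index = circ), fs, list())
  v <- tangential_speed(rec, "index", filter = FALSE)
  interior <- 20:460
  expect_equal(v[interior], rep(omega * radius, length(interior)),
               tolerance = 0.01 * omega * radius)
  # stationary marker: zero speed
  rec0 <- marker_recording(list(index = matrix(1, 480, 3)), fs, list())
  expect_equal(tangential_speed(rec0, "index", filter = FALSE),
               rep(0, 480))
  # invariance under rigid rotation of the frame
  th <- 0.83
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rec_rot <- marker_recording(list(index = circ %*% Rz), fs, list())
  expect_equal(tangential_speed(rec_rot, "index", filter = FALSE), v,
               tolerance = 1e-9)
  expect_error(tangential_speed(rec, "wrist"), "not present")
})

test_that("movement detection finds interpolated 5% crossings around the peak", {
  fs <- 120
  # symmetric triangular profile: onset/offset symmetric about the peak
  tri <- c(rep(0, 30), seq(0, 1, length.out = 49),
           seq(1, 0, length.out = 49)[-1], rep(0, 30))
  det <- detect_movement(tri, fs)
  peak_t <- det$peak_time
  expect_equal(peak_t - det$onset_time, det$offset_time - peak_t,
               tolerance = 1e-3)
  # oracle: exhaustive scan for the threshold crossings
  thr <- 0.05 * max(tri)
  above <- which(tri >= thr)
  expect_equal(det$onset_index, min(above))
  expect_equal(det$offset_index, max(above))
  # profiles that never move are rejected
  expect_error(detect_movement(rep(0, 200), fs), "peak")
  # multi-peaked profiles are flagged
  two <- c(rep(0, 20), dnorm(seq(-3, 3, length.out = 60)),
           rep(0, 10), dnorm(seq(-3, 3, length.out = 60)) * 0.8,
           rep(0, 20))
  expect_error(detect_movement(two, fs), "single-peaked")
})

test_that("a sampled minimum-jerk profile yields SR = 0.5 downstream", {
  fs <- 120
  tr <- solve_min_jerk(movement_task())
  v <- stats::approx(tr$times, abs(tr$velocity),
                     xout = seq(0, 0.4, by = 1 / fs))$y
  v <- c(rep(0, 30), v, rep(0, 30))
  det <- detect_movement(v, fs)
  sr <- (det$peak_time - det$onset_time) /
    (det$offset_time - det$onset_time)
  expect_equal(sr, 0.5, tolerance = 0.01)
})

test_that("feature extraction round-trips generated trials", {
  # noiseless trials across the SR range: extracted SR within 0.01
  for (target in c(0.35, 0.5, 0.65)) {
    cfg <- generator_config(sr_mode = "profile_driven",
                            profile_sr = target, marker_noise_sd = 0)
    f <- extract_features(generate_trial(cfg, list(gamma = -pi / 4),
                                         seed = 3))
    expect_lt(abs(f$symmetry_ratio - target), 0.01)
  }
  # amplitude exactly 45 deg, zero noise: final error below 0.1 deg
  cfg <- generator_config(sr_mode = "profile_driven", marker_noise_sd = 0)
  f <- extract_features(generate_trial(cfg, list(gamma = pi / 3),
                                       seed = 5))
  expect_lt(abs(f$final_angle_error), 0.1)
  # 0.5 mm marker noise moves SR by < 0.02
  cfgn <- generator_config(sr_mode = "profile_driven", profile_sr = 0.45)
  devs <- vapply(1:12, function(s) {
    extract_features(generate_trial(cfgn, list(gamma = -pi / 4),
                                    seed = s))$symmetry_ratio
  }, numeric(1))
  expect_lt(max(abs(devs - 0.45)), 0.02)
})

test_that("SR is invariant to time and amplitude rescaling of the profile", {
  cfg1 <- generator_config(sr_mode = "profile_driven", profile_sr = 0.42,
                           marker_noise_sd = 0)
  f1 <- extract_features(generate_trial(
    cfg1, list(gamma = 0, duration = 0.40), seed = 2))
  f2 <- extract_features(generate_trial(
    cfg1, list(gamma = 0, duration = 0.80), seed = 2))
  f3 <- extract_features(generate_trial(
    cfg1, list(gamma = 0, duration = 0.40, amplitude = pi / 8), seed = 2))
  expect_lt(abs(f1$symmetry_ratio - f2$symmetry_ratio), 0.01)
  expect_lt(abs(f1$symmetry_ratio - f3$symmetry_ratio), 0.01)
})

test_that("features are bit-identical for the same recording", {
  cfg <- generator_config(sr_mode = "profile_driven")
  rec <- generate_trial(cfg, list(gamma = pi / 6), seed = 9)
  expect_identical(extract_features(rec), extract_features(rec))
})

test_that("error aggregation computes SE as mean and VE as sample SD", {
  base <- tibble::tibble(
    trial_id = c("a", "b"), subject_id = "S01", gamma = 90,
    phase = "1g", symmetry_ratio = c(0.5, 0.5),
    movement_duration = 0.4, peak_speed = 2,
    final_angle_error = c(1, -1), onset_index = 1L, offset_index = 2L)
  agg <- aggregate_errors(base)
  expect_equal(agg$systematic_error, 0)
  expect_equal(agg$variable_error, sqrt(2))   # sample SD of (+1, -1)
  # identical trials: VE = 0
  base2 <- base
  base2$final_angle_error <- c(0.7, 0.7)
  expect_equal(aggregate_errors(base2)$variable_error, 0)
  # a 1-trial cell is rejected
  expect_error(aggregate_errors(base[1, ]), "2 trials")
})

test_that("generated error structure is recovered at the cell level", {
  # trials built with known SE and VE in the final angle
  set.seed(42)
  n <- 12
  cfg <- generator_config(sr_mode = "profile_driven", marker_noise_sd = 0)
  errs <- 1 + 2 * rnorm(n)  # degrees: SE = 1, VE = 2
  feats <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    amp <- pi / 4 + errs[i] * pi / 180
    extract_features(generate_trial(
      cfg, list(gamma = pi / 2, amplitude = amp,
                trial_id = sprintf("T%02d", i)), seed = 100 + i),
      task = movement_task())
  }))
  agg <- aggregate_errors(feats)
  expect_equal(agg$systematic_error, mean(errs), tolerance = 0.1)
  expect_equal(agg$variable_error, sd(errs), tolerance = 0.1)
})
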