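# Kinematic feature extraction for (synthetic) motion-capture recordings:
# zero-phase Butterworth filtering, finger tangential speed, velocity-
# threshold movement detection, and per-trial features.

#' Zero-phase low-pass Butterworth filter
#'
#' Fifth-order Butterworth low-pass filter (default cutoff 10 Hz), applied
#' forward and backward (zero phase, so onset and offset times are not
#' lag-shifted; the effective magnitude response is squared). The series is
#' extended by edge reflection before filtering to suppress end transients,
#' and the extension is discarded, so the output length equals the input
#' length.
#'
#' @param x Numeric series (or matrix: columns filtered independently).
#' @param sample_rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz). Default 10.
#' @param order Filter order. Default 5.
#' @return Filtered series, same shape as `x`.
#' @export
#' @examples
#' t <- (0:239) / 120
#' x <- sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 45 * t)
#' y <- lowpass(x, 120)   # 45 Hz component removed
lowpass <- function(x, sample_rate, cutoff = 10, order = 5) {
  stopifnot(is.numeric(sample_rate), sample_rate > 0,
            cutoff > 0, cutoff < sample_rate / 2)
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass, sample_rate = sample_rate,
                 cutoff = cutoff, order = order))
  }
  n <- length(x)
  pad <- min(n - 1L, 3L * (order + 1L) * as.integer(
    ceiling(sample_rate / cutoff)))
  if (n <= 3 * (order + 1)) {
    stop("series too short for the filter warm-up")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # reflect about the end points so the padded series is continuous
  head_pad <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Tangential speed of a marker
#'
#' Euclidean norm of the time derivative of the (filtered) 3-D marker
#' position, with derivatives by central differences (one-sided at the
#' ends).
#'
#' @param recording A [marker_recording()].
#' @param marker Marker label. Default `"index"` (the fingertip).
#' @param filter Apply [lowpass()] to the positions first? Default `TRUE`.
#' @return Speed series (m/s), one value per sample.
#' @export
tangential_speed <- function(recording, marker = "index", filter = TRUE) {
  stopifnot(inherits(recording, "marker_recording"))
  if (!marker %in% names(recording$positions)) {
    stop(sprintf("marker '%s' not present in recording (has: %s)",
                 marker, paste(names(recording$positions), collapse = ", ")))
  }
  pos <- recording$positions[[marker]]
  if (filter) pos <- lowpass(pos, recording$sample_rate)
  v <- central_diff(pos, 1 / recording$sample_rate)
  sqrt(rowSums(v^2))
}

# Central-difference derivative of a series or matrix (columns).
central_diff <- function(x, dt) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
    (dt * c(1, rep(2, n - 2), 1))
  d
}

#' Detect movement onset and offset from a speed profile
#'
#' Movement start and end are the times at which the speed goes above,
#' respectively falls below, `threshold_fraction` (default 5%) of the
#' maximum speed: the onset is the last up-crossing before the global
#' peak and the offset the first down-crossing after it. Returns both the
#' sample indices (first sample at or above threshold / last at or above)
#' and sub-sample crossing times by linear interpolation.
#'
#' Profiles with more than one local maximum exceeding 20% of the global
#' peak are rejected (the analyses assume single-peaked profiles).
#'
#' @param speed Speed series (non-negative).
#' @param sample_rate Sampling rate (Hz).
#' @param threshold_fraction Threshold as a fraction of peak speed.
#'   Default 0.05.
#' @param check_single_peak Reject multi-peaked profiles? Default `TRUE`.
#' @return A list with `onset_index`, `offset_index`, `peak_index`
#'   (1-based samples), `onset_time`, `offset_time`, `peak_time`
#'   (interpolated, s), and `peak_speed`.
#' @export
detect_movement <- function(speed, sample_rate, threshold_fraction = 0.05,
                            check_single_peak = TRUE) {
  stopifnot(is.numeric(speed), length(speed) >= 5, sample_rate > 0)
  if (check_single_peak && count_speed_peaks(speed) > 1L) {
    stop("speed profile is not single-peaked")
  }
  times <- (seq_along(speed) - 1) / sample_rate
  # indices on the original sample grid
  lm <- speed_landmarks(times, speed, threshold_fraction)
  # sub-sample landmark times from a spline-refined profile: the filtered
  # speed is band-limited well below Nyquist, so spline interpolation
  # recovers the continuous profile far better than per-sample resolution
  fine <- stats::spline(times, speed, n = 8L * length(speed))
  lmf <- speed_landmarks(fine$x, pmax(fine$y, 0), threshold_fraction)
  list(onset_index = lm$onset_index, offset_index = lm$offset_index,
       peak_index = lm$peak_index, onset_time = lmf$onset_time,
       offset_time = lmf$offset_time, peak_time = lmf$peak_time,
       peak_speed = lmf$peak_speed)
}

#' Extract per-trial kinematic features
#'
#' Chains the analysis pipeline on one recording: low-pass filtering of the
#' fingertip marker, tangential speed, threshold-based movement detection,
#' then the per-trial scalars: symmetry ratio (acceleration time divided by
#' movement time, from interpolated landmark times), movement duration,
#' peak speed, and the signed final angular error of the fingertip
#' elevation relative to the target amplitude (positive = overshoot along
#' the movement direction).
#'
#' @param recording A [marker_recording()].
#' @param task Optional [movement_task()] describing the intended movement;
#'   defaults to the task implied by the recording's condition metadata.
#' @return A one-row tibble with columns `trial_id`, `subject_id`,
#'   `gamma`, `phase`, `symmetry_ratio`, `movement_duration`, `peak_speed`,
#'   `final_angle_error`, `onset_index`, `offset_index`.
#' @export
extract_features <- function(recording, task = NULL) {
  stopifnot(inherits(recording, "marker_recording"))
  cond <- recording$condition
  if (is.null(task)) {
    task <- movement_task(theta_start = 0,
                          theta_end = cond$amplitude,
                          gamma = cond$gamma,
                          duration = max(cond$duration, 1e-3))
  }
  speed <- tryCatch(
    tangential_speed(recording, "index"),
    error = function(e) stop("tangential_speed stage failed: ",
                             conditionMessage(e)))
  det <- tryCatch(
    detect_movement(speed, recording$sample_rate),
    error = function(e) stop("detect_movement stage failed: ",
                             conditionMessage(e)))
  sr <- (det$peak_time - det$onset_time) /
    (det$offset_time - det$onset_time)

  # final fingertip elevation angle in the movement plane vs the target,
  # averaged over the settled posture at the end of the recording (the 5%
  # offset crossing still carries a small residual movement tail)
  ang <- movement_angle(recording)
  n <- length(ang)
  tail_n <- max(3L, as.integer(round(0.1 * recording$sample_rate)))
  tail_idx <- seq(max(det$offset_index, n - tail_n + 1L), n)
  final_err_deg <- (mean(ang[tail_idx]) - task$amplitude) * 180 / pi

  tibble::tibble(
    trial_id = cond$trial_id %||% NA_character_,
    subject_id = cond$subject_id %||% NA_character_,
    gamma = cond$gamma * 180 / pi,
    phase = cond$phase %||% NA_character_,
    symmetry_ratio = sr,
    movement_duration = det$offset_time - det$onset_time,
    peak_speed = det$peak_speed,
    final_angle_error = final_err_deg,
    onset_index = det$onset_index,
    offset_index = det$offset_index
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shoulder elevation angle of the index marker within the movement plane,
# measured from the initial arm direction (filtered positions).
movement_angle <- function(recording) {
  sh <- lowpass(recording$positions$shoulder, recording$sample_rate)
  ix <- lowpass(recording$positions$index, recording$sample_rate)
  rel <- ix - sh
  e0 <- recording$condition$plane_e0
  e1 <- recording$condition$plane_e1
  atan2(rel %*% e1, rel %*% e0)[, 1]
}

#' Aggregate final-error features into systematic and variable errors
#'
#' For each subject-by-direction (and phase, if present) cell: the
#' systematic error SE is the mean signed final angular error and the
#' variable error VE is the sample standard deviation of the signed error.
#'
#' @param features A tibble of per-trial features from
#'   [extract_features()] (rows bound together).
#' @return A tibble with one row per cell and columns `subject_id`,
#'   `gamma`, `phase`, `n_trials`, `systematic_error`, `variable_error`,
#'   `mean_sr`, `sd_sr`.
#' @export
aggregate_errors <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  out <- features |>
    dplyr::group_by(.data$subject_id, .data$gamma, .data$phase) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      systematic_error = mean(.data$final_angle_error),
      variable_error = stats::sd(.data$final_angle_error),
      mean_sr = mean(.data$symmetry_ratio),
      sd_sr = stats::sd(.data$symmetry_ratio),
      .groups = "drop"
    )
  if (any(out$n_trials < 2)) {
    stop("each subject x direction cell needs at least 2 trials")
  }
  out
}
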