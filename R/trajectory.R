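#' Construct a trajectory object
#'
#' A solved (or resampled measured) time course of a single-joint movement
#' on a uniform time grid: angle, angular velocity, acceleration and net
#' muscle torque, plus the value of the objective that produced it.
#'
#' @param times Uniform time grid over `[0, T]` (s).
#' @param angle,velocity,acceleration Angular kinematics (rad, rad/s,
#'   rad/s^2), same length as `times`.
#' @param torque Net muscle torque (N m), same length as `times`.
#' @param model Character tag of the generating cost model.
#' @param cost_value Achieved objective value (scalar, `NA` allowed).
#' @param task The [movement_task()] that was solved.
#' @param jerk Optional angular jerk series (rad/s^3).
#'
#' @return An object of class `arm_trajectory`.
#' @keywords internal
new_trajectory <- function(times, angle, velocity, acceleration, torque,
                           model, cost_value = NA_real_, task = NULL,
                           jerk = NULL) {
  n <- length(times)
  stopifnot(length(angle) == n, length(velocity) == n,
            length(acceleration) == n, length(torque) == n)
  structure(
    list(times = times, angle = angle, velocity = velocity,
         acceleration = acceleration, torque = torque, jerk = jerk,
         model = model, cost_value = cost_value, task = task),
    class = "arm_trajectory"
  )
}

#' @export
print.arm_trajectory <- function(x, ...) {
  cat(sprintf("<arm_trajectory> model = %s, %d nodes over [0, %.3g] s\n",
              x$model, length(x$times), max(x$times)))
  cat(sprintf("  angle %.2f -> %.2f deg; SR = %.4f; cost = %.6g\n",
              x$angle[1] * 180 / pi, x$angle[length(x$angle)] * 180 / pi,
              trajectory_sr(x), x$cost_value))
  invisible(x)
}

#' Tidy table of a trajectory
#'
#' @param traj An `arm_trajectory`.
#' @return A tibble with columns `time`, `angle`, `velocity`,
#'   `acceleration`, `torque`, `model`, `gamma` (degrees).
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "arm_trajectory"))
  tibble::tibble(
    time = traj$times, angle = traj$angle, velocity = traj$velocity,
    acceleration = traj$acceleration, torque = traj$torque,
    model = traj$model,
    gamma = if (is.null(traj$task)) NA_real_ else traj$task$gamma * 180 / pi
  )
}

# Landmarks of a single-peaked speed profile: interpolated threshold
# crossings (last up-crossing before the peak, first down-crossing after)
# and a parabolically refined peak time. Times and speeds must be aligned;
# the grid need not start at zero.
speed_landmarks <- function(times, speed, threshold_fraction = 0.05) {
  stopifnot(length(times) == length(speed), length(speed) >= 5,
            threshold_fraction > 0, threshold_fraction < 1)
  ip <- which.max(speed)
  vmax <- speed[ip]
  if (!is.finite(vmax) || vmax <= 0) {
    stop("speed profile has no positive peak")
  }
  thr <- threshold_fraction * vmax

  # parabolic refinement of the peak through its two neighbours
  peak_time <- times[ip]
  if (ip > 1 && ip < length(speed)) {
    y0 <- speed[ip - 1]; y1 <- speed[ip]; y2 <- speed[ip + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      delta <- 0.5 * (y0 - y2) / den
      peak_time <- times[ip] + delta * (times[ip + 1] - times[ip])
    }
  }

  cross_time <- function(i) {
    # linear interpolation of the threshold crossing between i and i+1
    times[i] + (thr - speed[i]) / (speed[i + 1] - speed[i]) *
      (times[i + 1] - times[i])
  }

  below_pre <- which(speed[seq_len(ip - 1)] < thr)
  if (length(below_pre) == 0L) {
    if (speed[1] >= thr) {
      onset_index <- 1L
      onset_time <- times[1]
    } else {
      stop("no onset crossing found before the speed peak")
    }
  } else {
    i <- max(below_pre)
    onset_index <- i + 1L
    onset_time <- cross_time(i)
  }

  post <- seq(ip, length(speed))
  below_post <- post[speed[post] < thr]
  if (length(below_post) == 0L) {
    if (speed[length(speed)] >= thr) {
      offset_index <- length(speed)
      offset_time <- times[length(speed)]
    } else {
      stop("no offset crossing found after the speed peak")
    }
  } else {
    j <- min(below_post) - 1L
    offset_index <- j
    offset_time <- cross_time(j)
  }

  list(onset_time = onset_time, offset_time = offset_time,
       peak_time = peak_time, onset_index = onset_index,
       offset_index = offset_index, peak_index = ip,
       peak_speed = vmax, threshold = thr)
}

# Count local speed maxima exceeding `fraction` of the global peak.
# Used as the single-peak inclusion criterion. Maxima separated only by a
# shallow valley (above `merge_depth` of the lower of the two peaks) are
# merged: flat-topped profiles with micro-ripple count as one peak, while
# genuinely bimodal profiles do not.
count_speed_peaks <- function(speed, fraction = 0.20,
                              merge_depth = 0.90) {
  n <- length(speed)
  if (n < 3) return(0L)
  thr <- fraction * max(speed)
  interior <- 2:(n - 1)
  is_max <- speed[interior] >= speed[interior - 1] &
    speed[interior] > speed[interior + 1] & speed[interior] > thr
  peaks <- interior[is_max]
  # collapse plateau runs to one representative
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) <= 1) return(length(peaks))
  count <- 1L
  for (i in 2:length(peaks)) {
    valley <- min(speed[peaks[i - 1]:peaks[i]])
    if (valley < merge_depth * min(speed[peaks[i - 1]], speed[peaks[i]])) {
      count <- count + 1L
    }
  }
  count
}

#' Symmetry ratio of a speed profile
#'
#' The symmetry ratio (SR) is the acceleration time divided by the total
#' movement time: `(t_peak - t_onset) / (t_offset - t_onset)`, with onset
#' and offset at 5% of peak speed (linearly interpolated between samples)
#' and the peak time refined parabolically. SR = 0.5 indicates a
#' temporally symmetric velocity profile.
#'
#' @param times Time grid (s).
#' @param speed Non-negative speed profile, single-peaked.
#' @param threshold_fraction Onset/offset threshold as a fraction of peak
#'   speed. Default 0.05.
#' @return SR (dimensionless, in (0, 1)).
#' @export
#' @examples
#' t <- seq(0, 0.4, length.out = 401)
#' v <- sin(pi * t / 0.4)^2          # symmetric profile
#' symmetry_ratio_of_profile(t, v)   # 0.5
symmetry_ratio_of_profile <- function(times, speed,
                                      threshold_fraction = 0.05) {
  lm <- speed_landmarks(times, speed, threshold_fraction)
  (lm$peak_time - lm$onset_time) / (lm$offset_time - lm$onset_time)
}

#' Symmetry ratio of a trajectory
#'
#' @param traj An `arm_trajectory`.
#' @param threshold_fraction Onset/offset threshold fraction. Default 0.05.
#' @return SR of the trajectory's speed profile.
#' @export
trajectory_sr <- function(traj, threshold_fraction = 0.05) {
  stopifnot(inherits(traj, "arm_trajectory"))
  symmetry_ratio_of_profile(traj$times, abs(traj$velocity),
                            threshold_fraction)
}
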