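# Synthetic motion-capture generator: single-DOF arm rotations embedded as
# rigid 3-D marker motion, sampled at 120 Hz with additive white marker
# noise, emulating an optoelectronic recording setup with five arm markers.

MARKER_FRACTIONS <- c(shoulder = 0, elbow = 0.45, wrist = 0.78,
                      hand = 0.88, index = 1.00)

#' Construct a marker recording
#'
#' @param positions Named list of n-by-3 matrices (m), one per marker
#'   label; all the same length.
#' @param sample_rate Sampling rate (Hz).
#' @param condition Named list of condition metadata (direction `gamma`,
#'   `amplitude`, `duration`, gravity levels, ids, seed, the in-plane
#'   basis vectors `plane_e0`/`plane_e1`, `arm_length`).
#' @return An object of class `marker_recording`.
#' @export
marker_recording <- function(positions, sample_rate, condition) {
  stopifnot(is.list(positions), length(positions) >= 1, sample_rate > 0)
  n <- unique(vapply(positions, nrow, integer(1)))
  if (length(n) != 1L) stop("all marker series must have the same length")
  structure(
    list(positions = positions, sample_rate = sample_rate,
         n_samples = n, condition = condition),
    class = "marker_recording"
  )
}

#' @export
print.marker_recording <- function(x, ...) {
  cat(sprintf(
    "<marker_recording> %d samples at %g Hz, markers: %s\n",
    x$n_samples, x$sample_rate, paste(names(x$positions), collapse = ", ")))
  if (!is.null(x$condition$gamma)) {
    cat(sprintf("  gamma = %.1f deg, phase = %s, trial = %s\n",
                x$condition$gamma * 180 / pi,
                x$condition$phase %||% "?", x$condition$trial_id %||% "?"))
  }
  invisible(x)
}

# In-plane orthonormal basis for a movement plane of inclination gamma:
# e0 along the initial (horizontal) arm direction, e1 the in-plane
# direction of increasing theta. gamma = -pi/2 maps e1 to vertical up.
plane_basis <- function(gamma) {
  list(e0 = c(1, 0, 0),
       e1 = c(0, cos(gamma), -sin(gamma)))
}

#' Configure the synthetic experiment generator
#'
#' Defaults emulate the two recorded experiments: a 1g session with 17
#' movement directions and 12 trials per direction per subject
#' (experiment 1), and a parabolic-flight session with up/down movements
#' across a 1g baseline plus five weightlessness parabolas (experiment 2).
#' The planner's internal gravity value per phase is a generator knob
#' distinct from the environmental gravity, so partially adapted planning
#' (movements planned with an out-of-date gravity estimate) can be
#' represented.
#'
#' @param n_subjects Number of subjects. Default 15.
#' @param trials_per_cell Trials per subject x direction (x phase) cell.
#'   Default 12.
#' @param directions Plane inclinations (rad). Default
#'   `direction_set(17)`.
#' @param duration_mean,duration_sd Movement duration distribution (s).
#'   Defaults 0.40 and 0.01 (truncated positive).
#' @param marker_noise_sd Marker position noise SD (m). Default `5e-4`.
#' @param sr_mode `"model_driven"` (angle profile from the Smooth-Effort
#'   optimum at the phase's internal gravity) or `"profile_driven"`
#'   (analytic single-peaked profile with a prescribed symmetry ratio).
#' @param profile_sr Target symmetry ratio for `profile_driven` trials.
#'   Default 0.5.
#' @param profile_concentration Concentration of the beta-shaped speed
#'   profile (larger = narrower bell). Default 4.
#' @param internal_g_schedule Internal gravity per phase (1g, P1..P5) for
#'   experiment 2 (m/s^2). Default `c(9.81, 7.5, 5.5, 3.5, 2.0, 1.0)`, a
#'   progressive decay emulating adaptation to weightlessness.
#' @param body_mass_range,arm_length_range Uniform sampling ranges for
#'   per-subject anthropometrics. Defaults 55-90 kg and 0.60-0.80 m.
#' @param rest_padding Still time prepended/appended to each trial (s).
#'   Default 0.3.
#' @param seed Root seed for all randomness. Default 1.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 15, trials_per_cell = 12,
                             directions = direction_set(17),
                             duration_mean = 0.40, duration_sd = 0.01,
                             marker_noise_sd = 5e-4,
                             sr_mode = c("model_driven", "profile_driven"),
                             profile_sr = 0.5, profile_concentration = 4,
                             internal_g_schedule =
                               c(9.81, 7.5, 5.5, 3.5, 2.0, 1.0),
                             body_mass_range = c(55, 90),
                             arm_length_range = c(0.60, 0.80),
                             rest_padding = 0.3, seed = 1) {
  sr_mode <- match.arg(sr_mode)
  stopifnot(n_subjects >= 1, trials_per_cell >= 1,
            length(directions) >= 1, duration_mean > 0, duration_sd >= 0,
            marker_noise_sd >= 0, profile_sr > 0, profile_sr < 1,
            profile_concentration > 0, rest_padding >= 0.1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_cell = as.integer(trials_per_cell),
         directions = directions, duration_mean = duration_mean,
         duration_sd = duration_sd, marker_noise_sd = marker_noise_sd,
         sr_mode = sr_mode, profile_sr = profile_sr,
         profile_concentration = profile_concentration,
         internal_g_schedule = internal_g_schedule,
         body_mass_range = body_mass_range,
         arm_length_range = arm_length_range,
         rest_padding = rest_padding, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# ---------------------------------------------------------------------------
# Angle time courses

# Measured symmetry ratio of a beta-density speed profile as the analysis
# pipeline defines it: the profile is embedded as noiseless circular
# marker motion, sampled, low-pass filtered (the 10 Hz zero-phase
# Butterworth slightly symmetrizes skewed bells), differentiated, and the
# 5%-threshold landmarks extracted.
beta_profile_measured_sr <- function(mode, concentration,
                                     duration = 0.40, sample_rate = 120,
                                     pad = 0.3, arm_length = 0.70) {
  a <- 1 + mode * concentration
  b <- 1 + (1 - mode) * concentration
  n_pad <- as.integer(round(pad * sample_rate))
  n_move <- as.integer(round(duration * sample_rate))
  s <- seq(0, 1, length.out = n_move + 1L)
  theta <- (pi / 4) * c(rep(0, n_pad), stats::pbeta(s, a, b),
                        rep(1, n_pad))
  pos <- arm_length * cbind(cos(theta), sin(theta), 0)
  posf <- lowpass(pos, sample_rate)
  v <- sqrt(rowSums(central_diff(posf, 1 / sample_rate)^2))
  det <- detect_movement(v, sample_rate, check_single_peak = FALSE)
  (det$peak_time - det$onset_time) / (det$offset_time - det$onset_time)
}

# Invert the measured SR of the beta profile (cached per target) so the
# generated trial's ground-truth SR -- as the extraction pipeline defines
# it -- equals the target.
beta_profile_for_sr <- function(sr_target, concentration) {
  key <- sprintf("beta|%.6f|%.6f", sr_target, concentration)
  if (!is.null(.armplan_cache[[key]])) return(.armplan_cache[[key]])
  f <- function(m) beta_profile_measured_sr(m, concentration) - sr_target
  root <- stats::uniroot(f, c(0.05, 0.95), tol = 1e-6)
  m <- root$root
  ab <- c(a = 1 + m * concentration, b = 1 + (1 - m) * concentration)
  .armplan_cache[[key]] <- ab
  ab
}

# Angle profile theta(t_frac in [0,1]) for one trial; returns a function.
plan_angle_profile <- function(cfg, amplitude, duration, gamma,
                               internal_g, params) {
  if (cfg$sr_mode == "profile_driven") {
    ab <- beta_profile_for_sr(cfg$profile_sr, cfg$profile_concentration)
    function(s) amplitude * stats::pbeta(s, ab[["a"]], ab[["b"]])
  } else {
    # Smooth-Effort optimum at the planner's internal gravity. Solved once
    # per (subject, direction, g) at the nominal duration and rescaled in
    # time for per-trial duration jitter (the symmetry ratio is invariant
    # to uniform time rescaling).
    pg <- params
    pg$gravity <- internal_g
    task <- movement_task(theta_start = 0, theta_end = amplitude,
                          gamma = gamma, duration = cfg$duration_mean)
    tr <- cached_smooth_effort(task, pg)
    function(s) {
      stats::approx(tr$times / cfg$duration_mean, tr$angle, xout = s,
                    rule = 2)$y
    }
  }
}

# Package-level memoization of Smooth-Effort solves (used by the generator
# and by the internal-gravity fit, where the same trajectories recur).
.armplan_cache <- new.env(parent = emptyenv())

solver_cache_key <- function(task, params, spec) {
  paste(signif(c(task$theta_start, task$theta_end, task$gamma,
                 task$duration, params$arm_mass, params$lever_arm,
                 params$inertia, params$friction, params$gravity,
                 spec$alpha, spec$effort_smoothing, spec$n_basis,
                 spec$n_quad), 12), collapse = "|")
}

cached_smooth_effort <- function(task, params,
                                 spec = cost_spec("smooth_effort")) {
  key <- solver_cache_key(task, params, spec)
  if (!is.null(.armplan_cache[[key]])) return(.armplan_cache[[key]])
  tr <- solve_smooth_effort(task, params, spec)
  .armplan_cache[[key]] <- tr
  tr
}

#' Clear the package's trajectory cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_solver_cache <- function() {
  n <- length(ls(.armplan_cache))
  rm(list = ls(.armplan_cache), envir = .armplan_cache)
  invisible(n)
}

# ---------------------------------------------------------------------------
# Trial generation

#' Generate one synthetic motion-capture trial
#'
#' Builds the planned single-joint angle time course (Smooth-Effort optimal
#' trajectory at the condition's internal gravity, or an analytic
#' beta-shaped profile with prescribed symmetry ratio), embeds it as rigid
#' motion of five arm markers on a sphere of radius arm-length about the
#' shoulder in the plane of inclination `gamma`, samples at 120 Hz with
#' rest padding at both ends, and adds white Gaussian marker noise. Fully
#' reproducible from `seed`.
#'
#' @param cfg A [generator_config()].
#' @param condition Named list with at least `gamma` (rad); optional
#'   `amplitude` (rad, default `pi/4`), `duration` (s, default drawn from
#'   the config's duration distribution), `internal_g` (default 9.81),
#'   `gravity_env` (default 9.81), `phase`, `subject_id`, `trial_id`,
#'   `body_mass`, `arm_length`, `sr_target` (overrides the config's
#'   `profile_sr`).
#' @param seed Integer seed for this trial.
#' @param sample_rate Sampling rate (Hz). Default 120.
#' @return A [marker_recording()].
#' @export
#' @examples
#' cfg <- generator_config(sr_mode = "profile_driven")
#' rec <- generate_trial(cfg, list(gamma = -pi / 2), seed = 42)
#' extract_features(rec)$symmetry_ratio
generate_trial <- function(cfg, condition, seed, sample_rate = 120) {
  stopifnot(inherits(cfg, "generator_config"), is.list(condition))
  if (is.null(condition$gamma)) stop("condition must name a direction gamma")
  gamma <- condition$gamma
  if (!is.finite(gamma) || gamma < -pi / 2 - 1e-9 || gamma > pi / 2 + 1e-9) {
    stop("invalid condition: gamma outside [-pi/2, pi/2]")
  }
  amplitude <- condition$amplitude %||% (pi / 4)
  internal_g <- condition$internal_g %||% 9.81
  gravity_env <- condition$gravity_env %||% 9.81
  body_mass <- condition$body_mass %||% 70
  arm_length <- condition$arm_length %||% 0.70
  params <- anthropometrics_from_body(body_mass, arm_length)

  rng <- local_rng(seed)
  duration <- condition$duration %||%
    truncated_normal(1, cfg$duration_mean, cfg$duration_sd, rng)

  cfg_trial <- cfg
  if (!is.null(condition$sr_target)) cfg_trial$profile_sr <- condition$sr_target
  profile <- plan_angle_profile(cfg_trial, amplitude, duration, gamma,
                                internal_g, params)

  dt <- 1 / sample_rate
  n_pad <- as.integer(round(cfg$rest_padding * sample_rate))
  n_move <- as.integer(round(duration * sample_rate))
  t_move <- seq(0, 1, length.out = n_move + 1L)
  theta <- c(rep(0, n_pad), profile(t_move), rep(profile(1), n_pad))

  basis <- plane_basis(gamma)
  shoulder0 <- c(0, 0, 1.4)  # nominal shoulder height; arbitrary origin
  n <- length(theta)
  dir_mat <- outer(cos(theta), basis$e0) + outer(sin(theta), basis$e1)
  positions <- lapply(MARKER_FRACTIONS, function(fr) {
    pos <- matrix(rep(shoulder0, each = n), n, 3) +
      fr * arm_length * dir_mat
    if (cfg$marker_noise_sd > 0) {
      pos <- pos + matrix(rng$norm(3 * n, sd = cfg$marker_noise_sd), n, 3)
    }
    pos
  })
  names(positions) <- names(MARKER_FRACTIONS)

  marker_recording(
    positions = positions, sample_rate = sample_rate,
    condition = list(
      gamma = gamma, amplitude = amplitude, duration = duration,
      internal_g = internal_g, gravity_env = gravity_env,
      phase = condition$phase %||% "1g",
      subject_id = condition$subject_id %||% "S01",
      trial_id = condition$trial_id %||% "T001",
      body_mass = body_mass, arm_length = arm_length,
      seed = seed, plane_e0 = basis$e0, plane_e1 = basis$e1,
      sr_mode = cfg$sr_mode)
  )
}

# Self-contained RNG stream (L'Ecuyer-CMRG via set.seed on a private
# state) so trial generation never disturbs the caller's RNG.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    out <- f(...)
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) {
      with_state(stats::rnorm, n, mean, sd)
    },
    unif = function(n, min = 0, max = 1) {
      with_state(stats::runif, n, min, max)
    },
    sample = function(x) with_state(sample, x)
  )
}

truncated_normal <- function(n, mean, sd, rng) {
  x <- rng$norm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rng$norm(sum(x <= 0), mean, sd)
  x
}

# Deterministic per-trial seed derivation from the root seed.
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + index * 16807) %% 2147483647L)
}

# ---------------------------------------------------------------------------
# Experiment designs

#' Generate a synthetic 17-direction 1g experiment
#'
#' Full factorial subjects x directions x trials (default 15 x 17 x 12 =
#' 3060 trials, 204 per subject), with per-subject anthropometrics drawn
#' uniformly from the configured ranges, per-trial durations from a
#' truncated normal, and trial order randomized within subject.
#'
#' @param cfg A [generator_config()].
#' @return A `recording_set`: list with `recordings` (list of
#'   [marker_recording()]), `manifest` (tibble), `config`.
#' @export
generate_experiment1 <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  rng <- local_rng(cfg$seed)
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  body_mass <- rng$unif(cfg$n_subjects, cfg$body_mass_range[1],
                        cfg$body_mass_range[2])
  arm_length <- rng$unif(cfg$n_subjects, cfg$arm_length_range[1],
                         cfg$arm_length_range[2])

  recordings <- list()
  rows <- list()
  idx <- 0L
  for (s in seq_along(subjects)) {
    cells <- expand.grid(direction = seq_along(cfg$directions),
                         trial = seq_len(cfg$trials_per_cell))
    order_idx <- rng$sample(nrow(cells))
    cells <- cells[order_idx, , drop = FALSE]
    for (r in seq_len(nrow(cells))) {
      idx <- idx + 1L
      gamma <- cfg$directions[cells$direction[r]]
      seed_t <- derive_seed(cfg$seed, idx)
      cond <- list(gamma = gamma, phase = "1g",
                   internal_g = 9.81, gravity_env = 9.81,
                   subject_id = subjects[s],
                   trial_id = sprintf("%s_T%04d", subjects[s], r),
                   body_mass = body_mass[s], arm_length = arm_length[s])
      rec <- generate_trial(cfg, cond, seed_t)
      recordings[[idx]] <- rec
      rows[[idx]] <- tibble::tibble(
        trial_id = rec$condition$trial_id, subject_id = subjects[s],
        gamma = gamma * 180 / pi, phase = "1g",
        duration = rec$condition$duration, seed = seed_t)
    }
  }
  structure(list(recordings = recordings,
                 manifest = dplyr::bind_rows(rows), config = cfg),
            class = "recording_set")
}

#' Generate a synthetic parabolic-flight adaptation experiment
#'
#' Up/down movement pairs across six phases (1g baseline, then parabolas
#' P1..P5), generated with the planner's internal gravity following
#' `cfg$internal_g_schedule` while the environmental gravity is 9.81 for
#' the baseline and 0 during parabolas (recorded as metadata; the planned
#' profile is what the internal model dictates).
#'
#' @param cfg A [generator_config()]; `trials_per_cell` defaults are
#'   usually set to about 15 for this design.
#' @return A `recording_set`.
#' @export
generate_experiment2 <- function(cfg = generator_config(
                                   n_subjects = 11, trials_per_cell = 15,
                                   directions = c(-pi / 2, pi / 2))) {
  stopifnot(inherits(cfg, "generator_config"))
  phases <- c("1g", paste0("P", 1:5))
  if (length(cfg$internal_g_schedule) != length(phases)) {
    stop("`internal_g_schedule` must have 6 entries (1g, P1..P5)")
  }
  if (length(cfg$directions) != 2) {
    stop("experiment 2 uses exactly 2 directions (up, down)")
  }
  rng <- local_rng(cfg$seed + 1L)
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  body_mass <- rng$unif(cfg$n_subjects, cfg$body_mass_range[1],
                        cfg$body_mass_range[2])
  arm_length <- rng$unif(cfg$n_subjects, cfg$arm_length_range[1],
                         cfg$arm_length_range[2])

  recordings <- list()
  rows <- list()
  idx <- 0L
  for (s in seq_along(subjects)) {
    for (ph in seq_along(phases)) {
      for (d in seq_along(cfg$directions)) {
        for (tr in seq_len(cfg$trials_per_cell)) {
          idx <- idx + 1L
          seed_t <- derive_seed(cfg$seed + 1L, idx)
          cond <- list(
            gamma = cfg$directions[d], phase = phases[ph],
            internal_g = cfg$internal_g_schedule[ph],
            gravity_env = if (phases[ph] == "1g") 9.81 else 0,
            subject_id = subjects[s],
            trial_id = sprintf("%s_%s_D%d_T%02d", subjects[s],
                               phases[ph], d, tr),
            body_mass = body_mass[s], arm_length = arm_length[s])
          rec <- generate_trial(cfg, cond, seed_t)
          recordings[[idx]] <- rec
          rows[[idx]] <- tibble::tibble(
            trial_id = rec$condition$trial_id, subject_id = subjects[s],
            gamma = cfg$directions[d] * 180 / pi, phase = phases[ph],
            internal_g = cfg$internal_g_schedule[ph],
            duration = rec$condition$duration, seed = seed_t)
        }
      }
    }
  }
  structure(list(recordings = recordings,
                 manifest = dplyr::bind_rows(rows), config = cfg),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d recordings, %d subjects\n",
              length(x$recordings),
              length(unique(x$manifest$subject_id))))
  invisible(x)
}
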