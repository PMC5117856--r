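# Plain-text persistence: long-format CSV for marker trajectories with a
# JSON sidecar for condition metadata, plus tidy CSV export of features
# and trajectories.

#' Write a recording set to disk
#'
#' Marker positions go to `<dir>/markers.csv` in long format (`trial_id`,
#' `time`, `marker`, `x`, `y`, `z`); condition metadata and per-trial
#' seeds go to `<dir>/manifest.json`.
#'
#' @param set A `recording_set` (see [generate_experiment1()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_recordings <- function(set, dir) {
  stopifnot(inherits(set, "recording_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- lapply(set$recordings, function(rec) {
    n <- rec$n_samples
    times <- (seq_len(n) - 1) / rec$sample_rate
    dplyr::bind_rows(lapply(names(rec$positions), function(m) {
      tibble::tibble(
        trial_id = rec$condition$trial_id, time = times, marker = m,
        x = rec$positions[[m]][, 1], y = rec$positions[[m]][, 2],
        z = rec$positions[[m]][, 3])
    }))
  })
  utils::write.csv(dplyr::bind_rows(tabs),
                   file.path(dir, "markers.csv"), row.names = FALSE)
  conditions <- lapply(set$recordings, function(rec) {
    cond <- rec$condition
    cond$plane_e0 <- NULL  # reconstructed from gamma on read
    cond$plane_e1 <- NULL
    c(cond, list(sample_rate = rec$sample_rate))
  })
  names(conditions) <- vapply(set$recordings,
                              function(r) r$condition$trial_id, "")
  jsonlite::write_json(conditions, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording set from disk
#'
#' Inverse of [write_recordings()]: rebuilds `marker_recording` objects
#' from the long-format CSV and the JSON sidecar.
#'
#' @param dir Directory written by [write_recordings()].
#' @return A `recording_set` (without the generator config).
#' @export
read_recordings <- function(dir) {
  mk <- utils::read.csv(file.path(dir, "markers.csv"))
  conditions <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
  recordings <- lapply(names(conditions), function(id) {
    cond <- as.list(conditions[[id]])
    sub <- mk[mk$trial_id == id, , drop = FALSE]
    positions <- lapply(split(sub, sub$marker), function(d) {
      d <- d[order(d$time), , drop = FALSE]
      cbind(d$x, d$y, d$z)
    })
    positions <- positions[intersect(names(MARKER_FRACTIONS),
                                     names(positions))]
    basis <- plane_basis(cond$gamma)
    cond$plane_e0 <- basis$e0
    cond$plane_e1 <- basis$e1
    sr <- cond$sample_rate
    cond$sample_rate <- NULL
    marker_recording(positions, sr, cond)
  })
  manifest <- tibble::tibble(
    trial_id = names(conditions),
    subject_id = vapply(conditions, function(c) c$subject_id, ""),
    gamma = vapply(conditions, function(c) c$gamma * 180 / pi, 0),
    phase = vapply(conditions, function(c) c$phase, ""))
  structure(list(recordings = recordings, manifest = manifest,
                 config = NULL),
            class = "recording_set")
}

#' Extract features for every recording in a set
#'
#' Runs [extract_features()] on each trial; unreadable trials are skipped
#' with a warning naming the trial and reason, and the run fails if more
#' than `max_skip_fraction` of trials are skipped.
#'
#' @param set A `recording_set`.
#' @param max_skip_fraction Maximum tolerated fraction of skipped trials.
#'   Default 0.05.
#' @return A tibble of per-trial features.
#' @export
extract_features_set <- function(set, max_skip_fraction = 0.05) {
  stopifnot(inherits(set, "recording_set"))
  if (length(set$recordings) == 0) stop("empty recording set")
  out <- vector("list", length(set$recordings))
  skipped <- character()
  for (i in seq_along(set$recordings)) {
    rec <- set$recordings[[i]]
    feat <- tryCatch(extract_features(rec), error = function(e) {
      warning(sprintf("skipping trial %s: %s",
                      rec$condition$trial_id %||% i,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(feat)) skipped <- c(skipped, rec$condition$trial_id %||% i)
    out[[i]] <- feat
  }
  if (length(skipped) > max_skip_fraction * length(set$recordings)) {
    stop(sprintf("%d of %d trials unreadable", length(skipped),
                 length(set$recordings)))
  }
  dplyr::bind_rows(out)
}
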