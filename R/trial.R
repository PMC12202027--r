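# Domain types: marker trajectories, trial recordings, frame intervals.
#
# Conventions used throughout the package:
#   * coordinates are right-handed, z vertical (up), units mm;
#   * frame indices are 0-based and intervals half-open [start, end);
#   * time in seconds is always frame / frame_rate, never resampled;
#   * a missing frame carries NA coordinates and is never treated as (0,0,0).

#' Construct a marker trajectory
#'
#' A trajectory is an n x 3 matrix (columns x, y, z, in mm) with one row per
#' frame. Missing frames are flagged and carry NA in all three coordinates.
#'
#' @param xyz numeric matrix with 3 columns (x, y, z in mm) or a vector of
#'   length 3n.
#' @param missing optional logical vector, one flag per frame. Defaults to
#'   frames containing any non-finite coordinate.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(xyz, missing = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  auto_missing <- !is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3])
  if (is.null(missing)) {
    missing <- auto_missing
  } else {
    stopifnot(length(missing) == nrow(xyz))
    missing <- as.logical(missing) | auto_missing
  }
  xyz[missing, ] <- NA_real_
  structure(xyz, missing = missing, class = c("trajectory", "matrix", "array"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory: %d frames, %d missing (%.1f%%)>\n",
    n_frames(x), sum(traj_missing(x)), 100 * mean(traj_missing(x))
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj)

#' Missing-frame flags of a trajectory
#' @param traj a `trajectory`.
#' @return logical vector, one flag per frame.
#' @export
traj_missing <- function(traj) attr(traj, "missing")

#' Frames filled by interpolation
#'
#' Flags set by [fill_short_gaps()]; all-FALSE for untouched trajectories.
#' @param traj a `trajectory`.
#' @return logical vector, one flag per frame.
#' @export
traj_filled <- function(traj) {
  f <- attr(traj, "filled")
  if (is.null(f)) rep(FALSE, n_frames(traj)) else f
}

# internal: rebuild a trajectory from a plain matrix, preserving/setting attrs
as_trajectory <- function(xyz, missing = NULL, filled = NULL) {
  t <- trajectory(xyz, missing)
  if (!is.null(filled)) attr(t, "filled") <- filled
  t
}

#' Marker pair table
#'
#' Pairs of markers implanted at a known physical separation, used to
#' quantify tracking accuracy.
#'
#' @param label_a,label_b marker labels (character).
#' @param known_distance known separations in mm (> 0).
#' @return data.frame with class `marker_pairs`.
#' @export
marker_pairs <- function(label_a, label_b, known_distance) {
  stopifnot(
    length(label_a) == length(label_b),
    length(label_a) == length(known_distance),
    all(known_distance > 0), all(label_a != label_b)
  )
  structure(
    data.frame(
      label_a = as.character(label_a), label_b = as.character(label_b),
      known_distance = as.numeric(known_distance), stringsAsFactors = FALSE
    ),
    class = c("marker_pairs", "data.frame")
  )
}

#' Frame interval table
#'
#' Half-open, 0-based frame intervals `[start, end)`.
#'
#' @param start,end integer frame indices, `0 <= start < end`.
#' @param n_frames optional total frame count used to validate `end`.
#' @return data.frame with columns `start`, `end`.
#' @export
frame_intervals <- function(start, end, n_frames = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == length(end), all(start >= 0), all(start < end))
  if (!is.null(n_frames)) stopifnot(all(end <= n_frames))
  data.frame(start = start, end = end)
}

# internal: 0-based [start, end) -> 1-based R row indices
interval_rows <- function(start, end) (start + 1L):end

#' Assemble a trial recording
#'
#' The unit of analysis: every marker trajectory of one behavioral trial,
#' together with its recording context.
#'
#' @param trial_id identifier string.
#' @param task one of `"OF"` (open field), `"CLB"` (wheel climbing),
#'   `"TRM"` (treadmill).
#' @param markers named list of [trajectory()] objects, one per body marker.
#' @param frame_rate frames per second (default 300).
#' @param surface_markers named list of trajectories of substrate markers
#'   (treadmill belt or wheel rim); may be empty.
#' @param known_pairs optional [marker_pairs()] table; every label must exist
#'   in `markers`.
#' @param residuals optional named list of per-frame triangulation residuals
#'   (mm), one numeric vector per marker.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(trial_id, task, markers, frame_rate = 300,
                            surface_markers = list(), known_pairs = NULL,
                            residuals = NULL) {
  task <- match.arg(task, c("OF", "CLB", "TRM"))
  stopifnot(frame_rate > 0, length(markers) >= 0)
  if (length(markers)) {
    stopifnot(!is.null(names(markers)), !anyDuplicated(names(markers)))
    lens <- vapply(markers, n_frames, integer(1))
    if (length(unique(lens)) > 1) {
      stop("all marker trajectories must have the same frame count")
    }
  }
  if (length(surface_markers)) {
    stopifnot(!is.null(names(surface_markers)))
    slens <- vapply(surface_markers, n_frames, integer(1))
    if (length(markers) && any(slens != n_frames(markers[[1]]))) {
      stop("surface-marker trajectories must match the trial frame count")
    }
    if (any(names(surface_markers) %in% names(markers))) {
      stop("surface-marker labels must not collide with body-marker labels")
    }
  }
  if (!is.null(known_pairs)) {
    labs <- unique(c(known_pairs$label_a, known_pairs$label_b))
    bad <- setdiff(labs, names(markers))
    if (length(bad)) stop("known_pairs references unknown markers: ", paste(bad, collapse = ", "))
  }
  if (!is.null(residuals)) {
    stopifnot(all(names(residuals) %in% names(markers)))
    rl <- vapply(residuals, length, integer(1))
    if (length(markers) && any(rl != n_frames(markers[[1]]))) {
      stop("residual series must match the trial frame count")
    }
  }
  structure(
    list(
      trial_id = as.character(trial_id), task = task,
      frame_rate = as.numeric(frame_rate), markers = markers,
      surface_markers = surface_markers, known_pairs = known_pairs,
      residuals = residuals
    ),
    class = "trial_recording"
  )
}

#' Frame count of a trial
#' @param trial a `trial_recording`.
#' @return integer number of frames.
#' @export
trial_frames <- function(trial) {
  if (length(trial$markers)) return(n_frames(trial$markers[[1]]))
  if (length(trial$surface_markers)) return(n_frames(trial$surface_markers[[1]]))
  0L
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording '%s': task %s, %d frames @ %g fps, %d markers, %d surface markers>\n",
    x$trial_id, x$task, trial_frames(x), x$frame_rate,
    length(x$markers), length(x$surface_markers)
  ))
  if (!is.null(x$known_pairs)) {
    cat(sprintf("  known pairs: %d\n", nrow(x$known_pairs)))
  }
  if (!is.null(x$residuals)) cat("  triangulation residuals present\n")
  invisible(x)
}

#' @export
summary.trial_recording <- function(object, ...) {
  vis <- vapply(object$markers, function(m) 100 * mean(!traj_missing(m)), numeric(1))
  out <- list(
    trial_id = object$trial_id, task = object$task,
    frames = trial_frames(object), frame_rate = object$frame_rate,
    duration_s = trial_frames(object) / object$frame_rate,
    visibility_pct = vis
  )
  class(out) <- "summary.trial_recording"
  out
}

#' @export
print.summary.trial_recording <- function(x, ...) {
  cat(sprintf(
    "Trial '%s' (%s): %.1f s at %g fps (%d frames)\n",
    x$trial_id, x$task, x$duration_s, x$frame_rate, x$frames
  ))
  cat("Marker visibility (%):\n")
  print(round(x$visibility_pct, 1))
  invisible(x)
}
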