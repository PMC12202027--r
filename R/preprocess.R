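# Trajectory repair: gap detection, linear interpolation of short gaps,
# and removal of short transient "jitter" glitches.
#
# Deliberately minimal: no smoothing or filtering of valid samples, since
# aggressive cleaning can remove real features of movement.

#' Locate tracking gaps in a trajectory
#'
#' Maximal runs of missing frames, each reported once. Gaps touching the
#' trial boundaries are flagged (they cannot be interpolated, which needs an
#' observed sample on both sides).
#'
#' @param traj a [trajectory()].
#' @param marker optional marker label carried into the output.
#' @return data.frame with 0-based half-open `start`/`end`,
#'   `duration_frames`, `boundary`, `filled` (always FALSE here).
#' @export
find_gaps <- function(traj, marker = NA_character_) {
  runs <- bool_runs(traj_missing(traj))
  runs <- runs[runs$value, , drop = FALSE]
  n <- n_frames(traj)
  data.frame(
    marker = rep(marker, nrow(runs)),
    start = runs$start - 1L,
    end = runs$end,
    duration_frames = runs$end - runs$start + 1L,
    boundary = runs$start == 1L | runs$end == n,
    filled = rep(FALSE, nrow(runs)),
    stringsAsFactors = FALSE
  )
}

#' Bridge short gaps by linear interpolation
#'
#' Interior gaps strictly shorter than `max_gap_frames` are replaced,
#' per axis, by linear interpolation between the flanking observed frames.
#' Longer gaps and gaps touching the trial boundaries are left missing.
#' Observed samples are never modified; interpolated frames are flagged so
#' that downstream kinematic measures can exclude them.
#'
#' @param traj a [trajectory()].
#' @param max_gap_frames fill gaps with `duration < max_gap_frames`
#'   (default 50 frames, ~165 ms at 300 fps).
#' @param marker optional marker label carried into the gap records.
#' @return list with `traj` (filled trajectory carrying a `filled` frame
#'   flag, see [traj_filled()]) and `gaps` (as [find_gaps()], with `filled`
#'   set for bridged gaps).
#' @export
fill_short_gaps <- function(traj, max_gap_frames = 50, marker = NA_character_) {
  stopifnot(max_gap_frames >= 1)
  gaps <- find_gaps(traj, marker)
  m <- unclass(traj)
  filled_mask <- traj_filled(traj)
  if (nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      if (gaps$boundary[i] || gaps$duration_frames[i] >= max_gap_frames) next
      rows <- interval_rows(gaps$start[i], gaps$end[i])
      i0 <- rows[1]
      i1 <- rows[length(rows)]
      for (k in 1:3) m[, k] <- interp_span(m[, k], i0, i1)
      filled_mask[rows] <- TRUE
      gaps$filled[i] <- TRUE
    }
  }
  missing <- !is.finite(m[, 1])
  list(
    traj = as_trajectory(m, missing = missing, filled = filled_mask),
    gaps = gaps
  )
}

# residual of x against a running median; window must exceed twice the
# maximal glitch width so glitches cannot drag the baseline
detrend_residual <- function(x, k = 9L) {
  ok <- is.finite(x)
  r <- rep(NA_real_, length(x))
  runs <- bool_runs(ok)
  for (i in which(runs$value)) {
    idx <- runs$start[i]:runs$end[i]
    seg <- x[idx]
    if (length(seg) >= k) {
      r[idx] <- seg - stats::runmed(seg, k)
    } else {
      r[idx] <- seg - stats::median(seg)
    }
  }
  r
}

#' Detect and remove short transient glitches ("jitter")
#'
#' A jitter event is a localized deviation exceeding `prominence_mm` in peak
#' prominence and lasting no more than `max_width_frames` frames. Each axis
#' is screened on its running-median residual; detected event frames,
#' together with their immediate neighbors, are replaced by linear
#' interpolation across the excised span. Wider deviations are left
#' untouched, as are events abutting missing data or the trial boundaries
#' (interpolating across missing data would fabricate structure). The
#' operation is idempotent on its own output.
#'
#' @param traj a [trajectory()].
#' @param prominence_mm detection threshold (default 0.05 mm).
#' @param max_width_frames maximal event width (default 3 frames, ~10 ms at
#'   300 fps).
#' @param marker optional marker label carried into the event records.
#' @return list with `traj` (repaired trajectory, same length and missing
#'   mask) and `events` (marker, axis, 0-based `frame` of the peak,
#'   `width_frames`, `prominence_mm`).
#' @export
remove_jitter <- function(traj, prominence_mm = 0.05, max_width_frames = 3,
                          marker = NA_character_) {
  stopifnot(prominence_mm > 0, max_width_frames >= 1)
  m <- unclass(traj)
  n <- nrow(m)
  events <- list()
  for (ax in 1:3) {
    x <- m[, ax]
    r <- detrend_residual(x)
    over <- is.finite(r) & abs(r) > prominence_mm
    runs <- bool_runs(over)
    runs <- runs[runs$value, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]
      e <- runs$end[i]
      if (e - s + 1L > max_width_frames) next
      # excise the run plus immediate neighbors; need finite anchors beyond
      i0 <- s - 1L
      i1 <- e + 1L
      if (i0 < 2L || i1 > n - 1L) next
      if (!all(is.finite(x[(i0 - 1L):(i1 + 1L)]))) next
      pk <- s - 1L + which.max(abs(r[s:e]))
      events[[length(events) + 1]] <- data.frame(
        marker = marker, axis = c("x", "y", "z")[ax], frame = pk - 1L,
        width_frames = e - s + 1L, prominence_mm = max(abs(r[s:e])),
        stringsAsFactors = FALSE
      )
      x <- interp_span(x, i0, i1)
    }
    m[, ax] <- x
  }
  list(
    traj = as_trajectory(m, missing = traj_missing(traj),
                         filled = attr(traj, "filled")),
    events = if (length(events)) do.call(rbind, events) else data.frame(
      marker = character(), axis = character(), frame = integer(),
      width_frames = integer(), prominence_mm = numeric(),
      stringsAsFactors = FALSE
    )
  )
}

#' Clean every marker of a trial
#'
#' Applies [fill_short_gaps()] then [remove_jitter()] to each body-marker
#' trajectory and collects the repair records.
#'
#' @param trial a [trial_recording()].
#' @param max_gap_frames as in [fill_short_gaps()].
#' @param jitter_prominence_mm,jitter_max_width_frames as in
#'   [remove_jitter()].
#' @return list with `trial` (cleaned), `gaps`, `jitter` (event tables
#'   across markers).
#' @export
clean_trial <- function(trial, max_gap_frames = 50,
                        jitter_prominence_mm = 0.05,
                        jitter_max_width_frames = 3) {
  gaps <- list()
  jit <- list()
  for (lab in names(trial$markers)) {
    fg <- fill_short_gaps(trial$markers[[lab]], max_gap_frames, marker = lab)
    rj <- remove_jitter(fg$traj, jitter_prominence_mm,
                        jitter_max_width_frames, marker = lab)
    trial$markers[[lab]] <- rj$traj
    if (nrow(fg$gaps)) gaps[[lab]] <- fg$gaps
    if (nrow(rj$events)) jit[[lab]] <- rj$events
  }
  list(
    trial = trial,
    gaps = if (length(gaps)) do.call(rbind, c(gaps, make.row.names = FALSE)) else data.frame(),
    jitter = if (length(jit)) do.call(rbind, c(jit, make.row.names = FALSE)) else data.frame()
  )
}
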