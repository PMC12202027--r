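# Tracking-quality metrics: visibility, gap-duration distributions,
# triangulation-residual summaries, known-distance tracking error, and
# spatial maps over the arena.
#
# All summaries ignore missing frames; nothing is imputed. Percentiles use
# the linear-interpolation definition (stats::quantile type 7) so results
# are reproducible. A frame is "locomotory" when it lies inside a detected
# locomotion episode; gaps are assigned to the state of their start frame.

episode_mask <- function(episodes, n) {
  mask <- logical(n)
  for (i in seq_len(NROW(episodes))) {
    mask[interval_rows(episodes$start[i], episodes$end[i])] <- TRUE
  }
  mask
}

#' Marker visibility
#'
#' @param trial a [trial_recording()] with at least one marker.
#' @return list with `per_frame_fraction` (visible markers / total markers,
#'   per frame) and `per_marker_pct` (percentage of frames each marker was
#'   tracked).
#' @export
marker_visibility <- function(trial) {
  if (!length(trial$markers)) stop("trial has no markers")
  vis <- vapply(trial$markers, function(m) !traj_missing(m),
    logical(trial_frames(trial))
  )
  vis <- matrix(vis, nrow = trial_frames(trial))
  list(
    per_frame_fraction = rowMeans(vis),
    per_marker_pct = stats::setNames(100 * colMeans(vis), names(trial$markers))
  )
}

#' Known-distance tracking error
#'
#' For each marker pair implanted at a known separation, the per-frame
#' tracking error is `| ||p_a - p_b|| - known_distance |`; frames where
#' either marker is missing are skipped (NA). Assuming both markers
#' contribute equally, the per-marker error is half the pairwise error
#' (averaged over the pairs a marker belongs to).
#'
#' @param trial a [trial_recording()] with a non-empty `known_pairs` table.
#' @return list with `per_pair` (n x n_pairs matrix of mm errors, columns
#'   named "a|b") and `per_marker` (named per-marker mean error, mm).
#' @export
pairwise_distance_error <- function(trial) {
  kp <- trial$known_pairs
  if (is.null(kp) || !nrow(kp)) stop("trial has no known marker pairs")
  nf <- trial_frames(trial)
  err <- matrix(NA_real_, nf, nrow(kp))
  colnames(err) <- paste(kp$label_a, kp$label_b, sep = "|")
  for (i in seq_len(nrow(kp))) {
    a <- unclass(trial$markers[[kp$label_a[i]]])
    b <- unclass(trial$markers[[kp$label_b[i]]])
    err[, i] <- abs(sqrt(rowSums((a - b)^2)) - kp$known_distance[i])
  }
  marker_err <- stats::setNames(numeric(0), character(0))
  for (lab in unique(c(kp$label_a, kp$label_b))) {
    cols <- which(kp$label_a == lab | kp$label_b == lab)
    e <- err[, cols, drop = FALSE] / 2
    marker_err[lab] <- mean(e[is.finite(e)])
  }
  list(per_pair = err, per_marker = marker_err)
}

state_split_summary <- function(values, loco_mask) {
  out <- list()
  for (state in c("locomotory", "stationary")) {
    v <- values[if (state == "locomotory") loco_mask else !loco_mask]
    v <- v[is.finite(v)]
    out[[state]] <- if (length(v)) {
      c(
        median = unname(stats::quantile(v, 0.5, type = 7)),
        p95 = unname(stats::quantile(v, 0.95, type = 7)),
        n = length(v)
      )
    } else {
      c(median = NA_real_, p95 = NA_real_, n = 0)
    }
  }
  out
}

#' Triangulation-residual summary split by behavioral state
#'
#' Residuals (mm) are pooled across frames and markers; the median and 95th
#' percentile are reported separately for locomotory and stationary frames.
#'
#' @param trial a [trial_recording()] carrying per-marker residual series.
#' @param episodes episode table from [detect_locomotion_episodes()].
#' @return list with `available` flag and, when available, per-state
#'   `median`/`p95`/`n`; an explicit not-available result (never zeros)
#'   when the trial has no residuals.
#' @export
residual_summary <- function(trial, episodes) {
  if (is.null(trial$residuals)) {
    return(list(available = FALSE))
  }
  nf <- trial_frames(trial)
  loco <- episode_mask(episodes, nf)
  vals <- unlist(lapply(trial$residuals, as.numeric), use.names = FALSE)
  mask <- rep(loco, times = length(trial$residuals))
  c(list(available = TRUE), state_split_summary(vals, mask))
}

#' Gap-duration distributions split by behavioral state
#'
#' Empirical cumulative distributions of gap durations for gaps starting in
#' locomotory vs stationary frames.
#'
#' @param gaps gap table from [find_gaps()] (possibly row-bound across
#'   markers).
#' @param episodes episode table from [detect_locomotion_episodes()].
#' @param n_frames trial frame count.
#' @return list per state with sorted `durations` and an `ecdf` function
#'   (NULL when that state has no gaps).
#' @export
gap_duration_distribution <- function(gaps, episodes, n_frames) {
  loco <- episode_mask(episodes, n_frames)
  out <- list()
  for (state in c("locomotory", "stationary")) {
    if (NROW(gaps)) {
      in_state <- loco[gaps$start + 1L] == (state == "locomotory")
      d <- sort(gaps$duration_frames[in_state])
    } else {
      d <- numeric(0)
    }
    out[[state]] <- list(
      durations = d,
      ecdf = if (length(d)) stats::ecdf(d) else NULL
    )
  }
  out
}

#' Spatial map of a per-frame metric over the arena
#'
#' Bins the arena into an `n_bins` x `n_bins` grid over the visited x/y
#' range and reports the mean of the metric over the frames whose reference
#' position falls into each bin. Bins never visited are NA (empty), not
#' zero. For mapping missing-marker counts, pass `smooth_frames = 100` to
#' apply the 100-frame moving average first.
#'
#' @param metric per-frame numeric values.
#' @param reference_xy n x 2 matrix of arena positions (mm), typically the
#'   hip midpoint.
#' @param n_bins bins per axis (default 20).
#' @param smooth_frames optional moving-average window applied to `metric`
#'   before binning.
#' @param range_xy optional list(x = c(lo, hi), y = c(lo, hi)) fixing the
#'   grid extent.
#' @return object of class `spatial_map`: list with `x_edges`, `y_edges`,
#'   `values`, `counts`.
#' @export
spatial_map <- function(metric, reference_xy, n_bins = 20, smooth_frames = NULL,
                        range_xy = NULL) {
  stopifnot(length(metric) == nrow(reference_xy))
  if (!is.null(smooth_frames)) metric <- moving_average(metric, smooth_frames)
  ok <- is.finite(metric) & is.finite(reference_xy[, 1]) & is.finite(reference_xy[, 2])
  x <- reference_xy[ok, 1]
  y <- reference_xy[ok, 2]
  v <- metric[ok]
  rx <- range_xy$x %||% range(x)
  ry <- range_xy$y %||% range(y)
  xe <- seq(rx[1], rx[2], length.out = n_bins + 1)
  ye <- seq(ry[1], ry[2], length.out = n_bins + 1)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), n_bins)
  values <- matrix(NA_real_, n_bins, n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  cell <- (iy - 1L) * n_bins + ix
  sums <- tapply(v, cell, sum)
  ns <- tapply(v, cell, length)
  idx <- as.integer(names(sums))
  values[idx] <- sums / ns
  counts[idx] <- as.integer(ns)
  structure(
    list(x_edges = xe, y_edges = ye, values = values, counts = counts),
    class = "spatial_map"
  )
}

#' @export
plot.spatial_map <- function(x, ...) {
  graphics::image(
    x = x$x_edges, y = x$y_edges, z = x$values,
    xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE, ...
  )
  invisible(x)
}

#' Full tracking-quality report for a trial
#'
#' @param trial a [trial_recording()].
#' @param episodes episode table from [detect_locomotion_episodes()].
#' @param gaps optional pooled gap table (computed from the trial markers
#'   when NULL).
#' @return object of class `quality_report`.
#' @export
quality_report <- function(trial, episodes, gaps = NULL) {
  nf <- trial_frames(trial)
  vis <- marker_visibility(trial)
  if (is.null(gaps)) {
    gaps <- do.call(rbind, lapply(names(trial$markers), function(lab) {
      find_gaps(trial$markers[[lab]], lab)
    }))
  }
  loco <- episode_mask(episodes, nf)
  pair <- if (!is.null(trial$known_pairs) && nrow(trial$known_pairs)) {
    pe <- pairwise_distance_error(trial)
    mask <- rep(loco, ncol(pe$per_pair))
    state_split_summary(c(pe$per_pair), mask)
  }
  structure(
    list(
      n_frames = nf,
      per_frame_visible_fraction = vis$per_frame_fraction,
      per_marker_visibility_pct = vis$per_marker_pct,
      visible_fraction_by_state = list(
        locomotory = vis$per_frame_fraction[loco],
        stationary = vis$per_frame_fraction[!loco]
      ),
      gap_durations_by_state = gap_duration_distribution(gaps, episodes, nf),
      residual_summary_by_state = residual_summary(trial, episodes),
      pairwise_error_by_state = pair
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report: %d frames; median visible fraction %.2f; 5th pct %.2f>\n",
    x$n_frames, stats::median(x$per_frame_visible_fraction),
    stats::quantile(x$per_frame_visible_fraction, 0.05, type = 7)
  ))
  if (!is.null(x$pairwise_error_by_state)) {
    cat(sprintf(
      "  tracking error (mm): loco median %.3f / p95 %.3f; stat median %.3f / p95 %.3f\n",
      x$pairwise_error_by_state$locomotory["median"],
      x$pairwise_error_by_state$locomotory["p95"],
      x$pairwise_error_by_state$stationary["median"],
      x$pairwise_error_by_state$stationary["p95"]
    ))
  }
  invisible(x)
}
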