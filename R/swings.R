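# Limb-swing detection in three locomotor contexts, and per-swing
# kinematic measures.
#
# Treadmill (TRM): continuous locomotion makes the vertical ankle
# trajectory cleanly periodic, so swings are the intervals between
# consecutive vertical minima. Open field (OF) and wheel climbing (CLB):
# non-locomotor limb movements make vertical position alone unreliable, so
# swings are delimited by the acceleration and deceleration peaks flanking
# high-speed ankle trajectories -- a locomotory step must generate
# propulsion, hence a distinct acceleration event. For CLB, ankle motion is
# expected to be substrate-relative (see [surface_relative()]).

# dominant frequency of a (possibly gappy) signal within a band
estimate_dominant_freq <- function(x, frame_rate, band = c(1, 15)) {
  runs <- bool_runs(is.finite(x))
  runs <- runs[runs$value, , drop = FALSE]
  if (!nrow(runs)) return(NA_real_)
  best <- which.max(runs$end - runs$start)
  seg <- x[runs$start[best]:runs$end[best]]
  if (length(seg) < 2 * frame_rate) return(NA_real_)
  ps <- welch_psd(seg, frame_rate, seg_len = min(length(seg), 2 * frame_rate))
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  ps$freq[sel][which.max(ps$power[sel])]
}

#' Detect ankle swings on the treadmill (vertical-minima method)
#'
#' Swing periods are the intervals between consecutive local minima of the
#' vertical ankle trajectory. Minima need a minimum prominence (to suppress
#' tremor-scale ripples) and a minimum separation, which defaults to half
#' the stride period estimated from the dominant frequency of the vertical
#' signal itself.
#'
#' @param ankle ankle [trajectory()], surface-relative, gaps filled.
#' @param frame_rate frames per second.
#' @param prominence_mm minimum prominence of a delimiting minimum
#'   (default 1 mm).
#' @param min_separation_frames minimum frames between minima; default
#'   `0.5 * frame_rate / stride_frequency_estimate`.
#' @param smooth_frames moving-average window applied to z before minima
#'   detection (default 5 frames); detection only, metrics use raw data.
#' @return data.frame of swing events: 0-based half-open `start`/`end`,
#'   `peak_frame` (vertical maximum within the swing), `context = "TRM"`.
#' @export
detect_swings_treadmill <- function(ankle, frame_rate, prominence_mm = 1,
                                    min_separation_frames = NULL,
                                    smooth_frames = 5) {
  z <- unclass(ankle)[, 3]
  zs <- if (smooth_frames > 1) moving_average(z, smooth_frames) else z
  if (is.null(min_separation_frames)) {
    f0 <- estimate_dominant_freq(z, frame_rate)
    min_separation_frames <- if (is.finite(f0) && f0 > 0) {
      max(2, floor(0.5 * frame_rate / f0))
    } else {
      2
    }
  }
  mins <- find_peaks(-zs, min_prominence = prominence_mm,
                     min_separation = min_separation_frames)
  empty <- data.frame(
    start = integer(), end = integer(), peak_frame = integer(),
    context = character(), stringsAsFactors = FALSE
  )
  if (nrow(mins) < 2) return(empty)
  idx <- mins$index
  out <- data.frame(
    start = idx[-length(idx)] - 1L,
    end = idx[-1] - 1L,
    context = "TRM", stringsAsFactors = FALSE
  )
  out$peak_frame <- vapply(seq_len(nrow(out)), function(k) {
    rows <- interval_rows(out$start[k], out$end[k])
    zz <- z[rows]
    if (!any(is.finite(zz))) return(NA_integer_)
    as.integer(rows[which.max(zz)] - 1L)
  }, integer(1))
  out[, c("start", "end", "peak_frame", "context")]
}

#' Detect ankle swings by acceleration/deceleration peaks (OF, CLB)
#'
#' The 3D ankle speed is computed over a 30-frame (~100 ms) window;
#' candidate swings are stretches where the speed exceeds an adaptive
#' threshold (mean + 1 SD of the defined speed samples by default). Each
#' candidate is delimited by the acceleration peak preceding its fastest
#' frame (propulsion onset) and the deceleration peak following it (the
#' braking event that concludes the ankle's deceleration). Overlapping
#' candidates are merged.
#'
#' @param ankle ankle [trajectory()] (surface-relative for CLB), gaps
#'   filled.
#' @param frame_rate frames per second.
#' @param window_frames speed window (default 30 frames).
#' @param speed_threshold_mm_s high-speed threshold; default adaptive,
#'   mean + 1 SD.
#' @param accel_prominence prominence for acceleration-peak detection in
#'   mm/s^2; default half the SD of the acceleration series.
#' @param context `"OF"` or `"CLB"` label carried into the events.
#' @return data.frame of swing events as in [detect_swings_treadmill()].
#' @export
detect_swings_accel <- function(ankle, frame_rate, window_frames = 30,
                                speed_threshold_mm_s = NULL,
                                accel_prominence = NULL,
                                context = "OF") {
  sp <- as.numeric(windowed_speed(ankle, window_frames, frame_rate))
  n <- length(sp)
  empty <- data.frame(
    start = integer(), end = integer(), peak_frame = integer(),
    context = character(), stringsAsFactors = FALSE
  )
  fin <- is.finite(sp)
  if (!any(fin)) return(empty)
  if (is.null(speed_threshold_mm_s)) {
    speed_threshold_mm_s <- mean(sp[fin]) + stats::sd(sp[fin])
  }
  acc <- c(NA_real_, diff(sp)) * frame_rate
  if (is.null(accel_prominence)) {
    accel_prominence <- 0.5 * stats::sd(acc[is.finite(acc)])
  }
  apk <- find_peaks(acc, min_prominence = accel_prominence)$index
  dpk <- find_peaks(-acc, min_prominence = accel_prominence)$index
  runs <- bool_runs(fin & sp > speed_threshold_mm_s)
  runs <- runs[runs$value, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  z <- unclass(ankle)[, 3]
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    s <- runs$start[k]
    e <- runs$end[k]
    pk_sp <- s - 1L + which.max(sp[s:e]) # fastest frame of the segment
    before <- apk[apk <= pk_sp]
    start <- if (length(before)) max(before) else s
    after <- dpk[dpk >= pk_sp]
    end <- if (length(after)) min(after) else e
    c(start, end)
  })
  ev <- do.call(rbind, ev)
  # merge overlapping candidates
  ord <- order(ev[, 1])
  ev <- ev[ord, , drop = FALSE]
  merged <- list(ev[1, ])
  for (k in seq_len(nrow(ev))[-1]) {
    last <- merged[[length(merged)]]
    if (ev[k, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], ev[k, 2]))
    } else {
      merged[[length(merged)]] <- last
      merged <- c(merged, list(ev[k, ]))
    }
  }
  ev <- do.call(rbind, merged)
  out <- data.frame(
    start = ev[, 1] - 1L, end = ev[, 2], context = context,
    stringsAsFactors = FALSE
  )
  out$peak_frame <- vapply(seq_len(nrow(out)), function(k) {
    rows <- interval_rows(out$start[k], out$end[k])
    zz <- z[rows]
    if (!any(is.finite(zz))) return(NA_integer_)
    as.integer(rows[which.max(zz)] - 1L)
  }, integer(1))
  out[, c("start", "end", "peak_frame", "context")]
}

#' Kinematic measures of detected swings
#'
#' For each swing: duration; mean and maximum frame-by-frame ankle speed;
#' swing height (vertical extent for OF/TRM, or the amplitude along the
#' second principal component of the swing's own 3D trajectory for CLB,
#' which is invariant to the body's orientation around the wheel); swing
#' distance (straight line start to end); trajectory path length; and the
#' signed timing of the peak ankle speed relative to the vertical swing
#' peak. Swings containing missing or gap-interpolated frames are flagged
#' invalid and carry NA measures, since interpolated sections must not
#' enter kinematic features.
#'
#' @param events swing table from one of the detectors.
#' @param ankle the ankle [trajectory()] the events refer to.
#' @param frame_rate frames per second.
#' @param context `"OF"`, `"CLB"` or `"TRM"`; defaults to the events'
#'   context column.
#' @return the events table augmented with `valid`, `duration_s`,
#'   `mean_speed`, `max_speed`, `height_mm`, `distance_mm`,
#'   `path_length_mm`, `peak_speed_offset_s`.
#' @export
swing_metrics <- function(events, ankle, frame_rate, context = NULL) {
  m <- unclass(ankle)
  missing <- traj_missing(ankle)
  filled <- traj_filled(ankle)
  n_ev <- nrow(events)
  out <- events
  cols <- c(
    "duration_s", "mean_speed", "max_speed", "height_mm", "distance_mm",
    "path_length_mm", "peak_speed_offset_s"
  )
  for (cc in cols) out[[cc]] <- NA_real_
  out$valid <- rep(FALSE, n_ev)
  for (k in seq_len(n_ev)) {
    ctx <- context %||% events$context[k]
    rows <- interval_rows(events$start[k], events$end[k])
    if (any(missing[rows]) || any(filled[rows])) next
    p <- m[rows, , drop = FALSE]
    step <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    spd <- step * frame_rate
    out$valid[k] <- TRUE
    out$duration_s[k] <- (events$end[k] - events$start[k]) / frame_rate
    out$mean_speed[k] <- mean(spd)
    out$max_speed[k] <- max(spd)
    out$height_mm[k] <- if (identical(ctx, "CLB")) {
      ctrd <- sweep(p, 2, colMeans(p))
      sc2 <- ctrd %*% svd(ctrd)$v[, 2]
      max(sc2) - min(sc2)
    } else {
      max(p[, 3]) - min(p[, 3])
    }
    out$distance_mm[k] <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    out$path_length_mm[k] <- sum(step)
    pk <- events$peak_frame[k]
    if (is.finite(pk)) {
      spd_frame <- rows[-length(rows)][which.max(spd)] - 1L # 0-based
      out$peak_speed_offset_s[k] <- (spd_frame - pk) / frame_rate
    }
  }
  out
}

#' Distribution of peak-ankle-speed timing
#'
#' Signed offsets of the fastest ankle movement relative to the vertical
#' swing peak, pooled over valid swings.
#'
#' @param metrics table from [swing_metrics()].
#' @return list with `offsets_s`, `median_s`, `q25_s`, `q75_s`, `n`.
#' @export
timing_histogram <- function(metrics) {
  off <- metrics$peak_speed_offset_s[metrics$valid &
    is.finite(metrics$peak_speed_offset_s)]
  if (!length(off)) stop("no valid swing events")
  q <- stats::quantile(off, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(offsets_s = off, median_s = q[2], q25_s = q[1], q75_s = q[3], n = length(off))
}
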