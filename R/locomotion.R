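# Locomotion measures: reference-point speed, locomotory-episode
# segmentation, whole-trial summaries, surface-relative motion on the
# treadmill belt and climbing wheel, and head-plane orientation.

#' Hip-midpoint reference trajectory
#'
#' The arithmetic midpoint of the two hip markers, used as the body
#' reference point for locomotion tracking. The midpoint is missing
#' wherever either hip marker is missing.
#'
#' @param trial a [trial_recording()].
#' @param hip_labels the two hip-marker labels.
#' @return a [trajectory()].
#' @export
hip_midpoint <- function(trial, hip_labels = c("hip_L", "hip_R")) {
  miss <- setdiff(hip_labels, names(trial$markers))
  if (length(miss)) stop("hip markers not found: ", paste(miss, collapse = ", "))
  a <- unclass(trial$markers[[hip_labels[1]]])
  b <- unclass(trial$markers[[hip_labels[2]]])
  trajectory((a + b) / 2)
}

#' Windowed speed of a trajectory
#'
#' Speed at frame t is the 3D displacement between the ends of a centered
#' window divided by the window duration:
#' `||p(t + ceil(w/2)) - p(t - floor(w/2))|| * frame_rate / w`.
#' Frames lacking a full window, or whose window endpoints are missing, are
#' undefined (NA).
#'
#' @param traj a [trajectory()].
#' @param window_frames window length in frames (>= 1).
#' @param frame_rate frames per second.
#' @param dims `3` for 3D displacement (default) or `2` for horizontal
#'   (x, y) displacement.
#' @return object of class `speed_series`: numeric mm/s per frame with
#'   attributes `window_frames`, `alignment`, `frame_rate`.
#' @export
windowed_speed <- function(traj, window_frames, frame_rate, dims = 3) {
  stopifnot(window_frames >= 1, frame_rate > 0, dims %in% c(2, 3))
  m <- unclass(traj)[, seq_len(dims), drop = FALSE]
  n <- nrow(m)
  w <- as.integer(window_frames)
  h1 <- w %/% 2L
  h2 <- w - h1
  v <- rep(NA_real_, n)
  idx <- seq_len(n)
  lo <- idx - h1
  hi <- idx + h2
  ok <- lo >= 1L & hi <= n
  d2 <- rowSums((m[pmin(hi, n), , drop = FALSE] - m[pmax(lo, 1L), , drop = FALSE])^2)
  v[ok] <- sqrt(d2[ok]) * frame_rate / w
  structure(v,
    window_frames = w, alignment = "centered", frame_rate = frame_rate,
    class = "speed_series"
  )
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf(
    "<speed_series: %d frames, %d-frame centered window, %.1f%% defined>\n",
    length(x), attr(x, "window_frames"), 100 * mean(is.finite(x))
  ))
  invisible(x)
}

#' Segment locomotory episodes from a speed series
#'
#' A locomotory episode is a maximal interval where the reference speed
#' exceeds `threshold`, tolerating interior sub-threshold dips of at most
#' `max_dip_frames` frames, and lasting (dips included) at least
#' `min_frames` frames. Episodes begin and end on supra-threshold frames;
#' undefined speed counts as sub-threshold.
#'
#' @param speed a [windowed_speed()] series or plain numeric vector (mm/s).
#' @param threshold speed threshold in mm/s (default 40).
#' @param min_frames minimum total episode length in frames (default 100).
#' @param max_dip_frames maximum tolerated interior dip length (default 50).
#' @return data.frame with 0-based half-open `start`/`end`,
#'   `duration_frames`, `mean_speed` (over defined frames in the episode).
#' @export
detect_locomotion_episodes <- function(speed, threshold = 40,
                                       min_frames = 100, max_dip_frames = 50) {
  stopifnot(threshold > 0, min_frames >= 1, max_dip_frames >= 0)
  v <- as.numeric(speed)
  above <- !is.na(v) & v > threshold
  runs <- bool_runs(above)
  up <- which(runs$value)
  if (!length(up)) {
    return(data.frame(
      start = integer(), end = integer(),
      duration_frames = integer(), mean_speed = numeric()
    ))
  }
  # merge consecutive supra-threshold runs across tolerable interior dips
  ep_start <- runs$start[up[1]]
  ep_end <- runs$end[up[1]]
  out <- list()
  flush <- function(s, e) {
    if (e - s + 1L >= min_frames) {
      vv <- v[s:e]
      out[[length(out) + 1]] <<- data.frame(
        start = s - 1L, end = e, duration_frames = e - s + 1L,
        mean_speed = mean(vv[is.finite(vv)])
      )
    }
  }
  if (length(up) > 1) {
    for (k in 2:length(up)) {
      dip <- runs$start[up[k]] - ep_end - 1L
      if (dip <= max_dip_frames) {
        ep_end <- runs$end[up[k]]
      } else {
        flush(ep_start, ep_end)
        ep_start <- runs$start[up[k]]
        ep_end <- runs$end[up[k]]
      }
    }
  }
  flush(ep_start, ep_end)
  if (!length(out)) {
    return(data.frame(
      start = integer(), end = integer(),
      duration_frames = integer(), mean_speed = numeric()
    ))
  }
  do.call(rbind, out)
}

#' Whole-trial locomotion summary
#'
#' @param traj reference-point [trajectory()] (typically [hip_midpoint()],
#'   surface-relative where applicable).
#' @param episodes episode table from [detect_locomotion_episodes()].
#' @param speed optional speed series used for the reported locomotory
#'   speed (the 1 s window of the paper); mean is taken over episode frames.
#' @param frame_rate frames per second.
#' @param bin_s bin width for the binned outputs (default 10 s).
#' @return list of class `locomotion_summary`: `distance_mm` (path length of
#'   the reference point over the whole trial), `time_locomoting_s`,
#'   `mean_locomotory_speed` (NA when the animal never locomoted), and a
#'   `binned` data.frame (per-bin distance and locomotion time).
#' @export
trial_locomotion_summary <- function(traj, episodes, speed = NULL,
                                     frame_rate, bin_s = 10) {
  m <- unclass(traj)
  n <- nrow(m)
  step <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  distance <- sum(step[is.finite(step)])
  time_loc <- sum(episodes$duration_frames) / frame_rate
  ep_frames <- logical(n)
  for (i in seq_len(nrow(episodes))) {
    ep_frames[interval_rows(episodes$start[i], episodes$end[i])] <- TRUE
  }
  mean_speed <- NA_real_
  if (!is.null(speed) && any(ep_frames)) {
    vv <- as.numeric(speed)[ep_frames]
    if (any(is.finite(vv))) mean_speed <- mean(vv[is.finite(vv)])
  } else if (is.null(speed) && nrow(episodes)) {
    mean_speed <- stats::weighted.mean(episodes$mean_speed, episodes$duration_frames)
  }
  bin <- floor((seq_len(n) - 1) / (bin_s * frame_rate))
  step_bin <- bin[-n]
  binned <- data.frame(
    bin_start_s = sort(unique(bin)) * bin_s,
    distance_mm = as.numeric(tapply(ifelse(is.finite(step), step, 0), step_bin,
      sum
    )[as.character(sort(unique(bin)))]),
    time_locomoting_s = as.numeric(tapply(ep_frames, bin, sum)) / frame_rate
  )
  binned$distance_mm[is.na(binned$distance_mm)] <- 0
  structure(
    list(
      distance_mm = distance, time_locomoting_s = time_loc,
      mean_locomotory_speed = mean_speed, binned = binned,
      n_episodes = nrow(episodes)
    ),
    class = "locomotion_summary"
  )
}

#' @export
print.locomotion_summary <- function(x, ...) {
  cat(sprintf(
    "Locomotion: %.0f mm traveled, %.1f s locomoting in %d episodes, mean speed %s mm/s\n",
    x$distance_mm, x$time_locomoting_s, x$n_episodes,
    if (is.na(x$mean_locomotory_speed)) "--" else sprintf("%.1f", x$mean_locomotory_speed)
  ))
  invisible(x)
}

# Rodrigues rotation of an n x 3 matrix about a unit axis through `center`
# by a per-frame angle vector.
rotate_about_axis <- function(m, center, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  v <- sweep(m, 2, center)
  ct <- cos(angle)
  st <- sin(angle)
  uxv <- cbind(
    u[2] * v[, 3] - u[3] * v[, 2],
    u[3] * v[, 1] - u[1] * v[, 3],
    u[1] * v[, 2] - u[2] * v[, 1]
  )
  udv <- v %*% u
  out <- v * ct + uxv * st + outer(c(udv) * (1 - ct), u)
  sweep(out, 2, center, `+`)
}

# least-squares (Kasa) circle fit; returns center (2) and radius
fit_circle <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  c(sol[1], sol[2], sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Re-express a trial relative to its moving substrate
#'
#' Treadmill (TRM): the belt's translational displacement is estimated from
#' the common motion of the belt markers along the belt axis (the principal
#' horizontal direction of their motion), with automatic handoff as markers
#' leave and enter the view, and subtracted from every body marker. Wheel
#' climbing (CLB): the wheel axis and center are fitted from the rim-marker
#' paths (plane fit, then circle fit) and every body marker is rotated back
#' by the rim's angular displacement.
#'
#' Frames where no surface marker yields a motion estimate are flagged
#' missing in the output. With zero substrate motion the transform is the
#' identity.
#'
#' @param trial a [trial_recording()] with task `"TRM"` or `"CLB"` and
#'   surface markers present.
#' @return a [trial_recording()] whose body-marker positions are
#'   substrate-relative; the substrate model is attached as attribute
#'   `surface_model`.
#' @export
surface_relative <- function(trial) {
  if (!trial$task %in% c("TRM", "CLB")) {
    stop("surface_relative applies to TRM and CLB trials")
  }
  if (!length(trial$surface_markers)) stop("no surface markers in trial")
  nf <- trial_frames(trial)
  smat <- lapply(trial$surface_markers, unclass)

  if (trial$task == "TRM") {
    # belt axis: principal horizontal direction of belt-marker displacement
    disp <- do.call(rbind, lapply(smat, function(m) {
      d <- m[-1, 1:2, drop = FALSE] - m[-nf, 1:2, drop = FALSE]
      d[is.finite(d[, 1]) & is.finite(d[, 2]), , drop = FALSE]
    }))
    if (!nrow(disp)) stop("belt markers never move; cannot estimate belt axis")
    ax2 <- svd(disp)$v[, 1]
    axis <- c(ax2, 0)
    # per-frame belt velocity: mean over markers visible at both t-1 and t
    vel <- matrix(NA_real_, nf - 1L, length(smat))
    for (j in seq_along(smat)) {
      m <- smat[[j]]
      d <- (m[-1, 1:2, drop = FALSE] - m[-nf, 1:2, drop = FALSE]) %*% ax2
      vel[, j] <- d
    }
    belt_step <- rowMeans(vel, na.rm = TRUE)
    undefined <- c(FALSE, !is.finite(belt_step))
    belt_step[!is.finite(belt_step)] <- 0
    belt_disp <- c(0, cumsum(belt_step))
    for (lab in names(trial$markers)) {
      m <- unclass(trial$markers[[lab]])
      m <- m - outer(belt_disp, axis)
      m[undefined, ] <- NA_real_
      trial$markers[[lab]] <- as_trajectory(
        m,
        filled = attr(trial$markers[[lab]], "filled")
      )
    }
    model <- list(kind = "belt", axis = axis, displacement_mm = belt_disp)
  } else {
    # wheel: plane fit of the rim cloud, then circle fit in-plane
    cloud <- do.call(rbind, lapply(smat, function(m) m[is.finite(m[, 1]), , drop = FALSE]))
    ctr <- colMeans(cloud)
    sv <- svd(sweep(cloud, 2, ctr))
    normal <- sv$v[, 3]
    e1 <- sv$v[, 1]
    e2 <- sv$v[, 2]
    uv <- sweep(cloud, 2, ctr) %*% cbind(e1, e2)
    circ <- fit_circle(uv)
    center <- ctr + circ[1] * e1 + circ[2] * e2
    # per-frame angular displacement, averaged over visible rim markers
    dth <- matrix(NA_real_, nf - 1L, length(smat))
    for (j in seq_along(smat)) {
      m <- smat[[j]]
      u <- sweep(m, 2, center) %*% cbind(e1, e2)
      ang <- atan2(u[, 2], u[, 1])
      d <- diff(ang)
      d <- (d + pi) %% (2 * pi) - pi # unwrap single steps
      dth[, j] <- d
    }
    step <- rowMeans(dth, na.rm = TRUE)
    undefined <- c(FALSE, !is.finite(step))
    step[!is.finite(step)] <- 0
    theta <- c(0, cumsum(step))
    for (lab in names(trial$markers)) {
      m <- unclass(trial$markers[[lab]])
      rel <- rotate_about_axis(m, center, normal, -theta)
      rel[undefined, ] <- NA_real_
      trial$markers[[lab]] <- as_trajectory(
        rel,
        filled = attr(trial$markers[[lab]], "filled")
      )
    }
    model <- list(
      kind = "wheel", center = center, axis = normal,
      radius = circ[3], theta_rad = theta
    )
  }
  attr(trial, "surface_model") <- model
  trial
}

#' Head-plane orientation from headplate corner markers
#'
#' Markers attached to the corners of a head-mounted plate define a 2D
#' plane; its orientation is reported per frame as yaw, pitch and roll
#' (z-y'-x'' Euler angles, degrees) of the plate's forward axis in the lab
#' frame (z up). Frames with fewer than 3 visible markers, or a degenerate
#' (collinear) marker set, are undefined.
#'
#' @param markers named list of >= 3 [trajectory()] objects.
#' @param front_labels,back_labels labels whose visible centroids define the
#'   forward direction (front minus back).
#' @return object of class `head_pose`: list with `angles` (data.frame yaw,
#'   pitch, roll in degrees) and `center` (n x 3 plane centroid, mm).
#' @export
head_orientation <- function(markers,
                             front_labels = grep("^f", names(markers), value = TRUE),
                             back_labels = grep("^b", names(markers), value = TRUE)) {
  stopifnot(length(markers) >= 3, length(front_labels) >= 1, length(back_labels) >= 1)
  nf <- n_frames(markers[[1]])
  mats <- lapply(markers, unclass)
  ang <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("yaw", "pitch", "roll")))
  ctr <- matrix(NA_real_, nf, 3)
  for (i in seq_len(nf)) {
    pts <- t(vapply(mats, function(m) m[i, ], numeric(3)))
    vis <- is.finite(pts[, 1])
    if (sum(vis) < 3) next
    p <- pts[vis, , drop = FALSE]
    c0 <- colMeans(p)
    sv <- svd(sweep(p, 2, c0))
    if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) next # collinear
    u <- sv$v[, 3]
    if (u[3] < 0) u <- -u # plate normal points up
    fl <- intersect(front_labels, rownames(pts)[vis])
    bl <- intersect(back_labels, rownames(pts)[vis])
    if (!length(fl) || !length(bl)) next
    fwd_raw <- colMeans(pts[fl, , drop = FALSE]) - colMeans(pts[bl, , drop = FALSE])
    fwd <- fwd_raw - u * sum(fwd_raw * u) # project into the plane
    nfwd <- sqrt(sum(fwd^2))
    if (nfwd < 1e-8) next
    f <- fwd / nfwd
    l <- c(
      u[2] * f[3] - u[3] * f[2],
      u[3] * f[1] - u[1] * f[3],
      u[1] * f[2] - u[2] * f[1]
    )
    R <- cbind(f, l, u)
    # yaw about z, then pitch (positive = nose up), then roll about the
    # forward axis
    ang[i, ] <- c(
      atan2(R[2, 1], R[1, 1]),
      asin(max(-1, min(1, R[3, 1]))),
      atan2(R[3, 2], R[3, 3])
    ) * 180 / pi
    ctr[i, ] <- c0
  }
  structure(
    list(angles = as.data.frame(ang), center = ctr),
    class = "head_pose"
  )
}

#' @export
print.head_pose <- function(x, ...) {
  ok <- is.finite(x$angles$yaw)
  cat(sprintf(
    "<head_pose: %d frames, %.1f%% defined>\n",
    nrow(x$angles), 100 * mean(ok)
  ))
  invisible(x)
}
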