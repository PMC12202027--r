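# Synthetic trial generator with full ground truth.
#
# Emulates the statistical structure the downstream analyses assume:
# intermittent locomotion episodes (alternating exponential walk/pause
# renewal process), stance/swing ankle cycles with a configurable
# peak-speed timing offset, additive whole-body tremor with per-marker
# phase offsets, a low-amplitude ~8 Hz breathing oscillation on the
# shoulder markers, rigid marker pairs at exact known spacing, white
# positional noise, occlusion gaps and short sub-0.1 mm glitches.
#
# All randomness flows from one explicit seed; repeated calls with the same
# config are byte-identical.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Ten-marker body layout: forward/lateral offsets from the body reference
# point and height above ground (mm). Every implanted pair is spaced 14 mm
# laterally; the ankle marker sits 14 mm above the heel and the knee ("upper
# leg") marker 28 mm, matching the implantation geometry.
marker_layout <- function() {
  lab <- c(
    "shoulder_L", "shoulder_R", "lumbar_L", "lumbar_R", "hip_L", "hip_R",
    "knee_L", "knee_R", "ankle_L", "ankle_R"
  )
  data.frame(
    label = lab,
    fwd = c(25, 25, 0, 0, -10, -10, -15, -15, -18, -18),
    lat = rep(c(-7, 7), 5),
    z = c(25, 25, 28, 28, 25, 25, 28, 28, 14, 14),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic trial generator
#'
#' Defaults describe a one-minute open-field trial recorded at 300 fps:
#' intermittent locomotion (mean walk 2 s at 150 mm/s, mean pause 3 s),
#' a 3 Hz stride with 10 mm swing arcs, 10 Hz whole-body tremor (off by
#' default), 8 Hz / 0.15 mm breathing on the shoulder markers, 0.01 mm
#' white positional noise, and sparse occlusion gaps and 0.1 mm glitches.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @param duration_s trial length in seconds.
#' @param frame_rate frames per second.
#' @param task `"OF"`, `"CLB"` or `"TRM"`.
#' @param arena_mm side length of the square arena (mm).
#' @param episode_model list: `mean_episode_s`, `mean_pause_s`,
#'   `speed_mm_s` (walking speed; also the belt/wheel surface speed).
#' @param gait_model list: `stride_hz`, `swing_height_mm`,
#'   `swing_duration_s`, `peak_speed_offset_s` (signed offset of the peak
#'   ankle speed relative to the vertical swing peak).
#' @param tremor_model list: `on`, `frequency_hz`, `amplitude_mm` (scalar or
#'   named per marker), `phase_rad` (scalar or named per marker).
#' @param breathing_model list: `on`, `frequency_hz`, `amplitude_mm`.
#' @param noise_sd white positional noise SD per axis (mm).
#' @param gap_model list: `rate_per_marker_min`, `mean_duration_frames`.
#' @param glitch_model list: `rate_per_marker_min`, `amplitude_mm`
#'   (<= 0.1), `max_width_frames` (<= 3).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, duration_s = 60, frame_rate = 300,
                             task = c("OF", "CLB", "TRM"), arena_mm = 300,
                             episode_model = list(), gait_model = list(),
                             tremor_model = list(), breathing_model = list(),
                             noise_sd = 0.01, gap_model = list(),
                             glitch_model = list()) {
  task <- match.arg(task)
  cfg <- list(
    seed = as.integer(seed), duration_s = duration_s,
    frame_rate = frame_rate, task = task, arena_mm = arena_mm,
    episode_model = utils::modifyList(
      list(mean_episode_s = 2, mean_pause_s = 3, speed_mm_s = 150),
      episode_model
    ),
    gait_model = utils::modifyList(
      list(
        stride_hz = 3, swing_height_mm = 10, swing_duration_s = 0.15,
        peak_speed_offset_s = 0.03
      ),
      gait_model
    ),
    tremor_model = utils::modifyList(
      list(on = FALSE, frequency_hz = 10, amplitude_mm = 0.2, phase_rad = 0),
      tremor_model
    ),
    breathing_model = utils::modifyList(
      list(on = TRUE, frequency_hz = 8, amplitude_mm = 0.15),
      breathing_model
    ),
    noise_sd = noise_sd,
    gap_model = utils::modifyList(
      list(rate_per_marker_min = 2, mean_duration_frames = 20),
      gap_model
    ),
    glitch_model = utils::modifyList(
      list(rate_per_marker_min = 2, amplitude_mm = 0.1, max_width_frames = 3),
      glitch_model
    )
  )
  stopifnot(
    cfg$frame_rate > 0, cfg$duration_s > 0, cfg$noise_sd >= 0,
    cfg$gap_model$rate_per_marker_min >= 0,
    cfg$glitch_model$rate_per_marker_min >= 0,
    cfg$episode_model$speed_mm_s >= 0, cfg$gait_model$stride_hz > 0
  )
  structure(cfg, class = "synthetic_config")
}

# cos^2 velocity pulse with unit integral, support width d centered at c
cos2_pulse <- function(t, c, d) {
  u <- (t - c) / d
  v <- ifelse(abs(u) < 0.5, cos(pi * u)^2, 0)
  v * 2 / d
}

#' Generate a synthetic trial with ground truth
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `trial` (a [trial_recording()]), `truth`
#'   (episodes, per-ankle swings, tremor parameters, injected gaps and
#'   glitches, plus the noise-free `clean` trial).
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    fr <- cfg$frame_rate
    nf <- as.integer(round(cfg$duration_s * fr))
    t <- (seq_len(nf) - 1) / fr
    lay <- marker_layout()
    em <- cfg$episode_model
    gm <- cfg$gait_model

    # ---- commanded body speed and episode schedule -----------------------
    v_cmd <- numeric(nf)
    walk_windows <- NULL # seconds, [start, end)
    if (em$speed_mm_s > 0 && cfg$task == "TRM") {
      v_cmd[] <- em$speed_mm_s # continuous running against the belt
      walk_windows <- data.frame(start = 0, end = cfg$duration_s)
    } else if (em$speed_mm_s > 0) {
      cur <- 0
      starts <- ends <- numeric(0)
      repeat {
        cur <- cur + stats::rexp(1, 1 / em$mean_pause_s)
        if (cur >= cfg$duration_s) break
        len <- stats::rexp(1, 1 / em$mean_episode_s)
        starts <- c(starts, cur)
        ends <- c(ends, min(cur + len, cfg$duration_s))
        cur <- cur + len
        if (cur >= cfg$duration_s) break
      }
      if (length(starts)) {
        walk_windows <- data.frame(start = starts, end = ends)
        ramp <- 0.2
        for (i in seq_len(nrow(walk_windows))) {
          s <- walk_windows$start[i]
          e <- walk_windows$end[i]
          idx <- t >= s & t < e
          prof <- rep(1, sum(idx))
          tt <- t[idx]
          up <- tt < s + ramp
          dn <- tt >= e - ramp
          prof[up] <- (1 - cos(pi * (tt[up] - s) / ramp)) / 2
          prof[dn] <- (1 - cos(pi * (e - tt[dn]) / ramp)) / 2
          v_cmd[idx] <- em$speed_mm_s * prof
        }
      }
    }

    # ---- body path -------------------------------------------------------
    margin <- 30
    if (cfg$task == "OF") {
      xy <- matrix(0, nf, 2)
      xy[1, ] <- cfg$arena_mm / 2
      th <- numeric(nf)
      th[1] <- stats::runif(1, 0, 2 * pi)
      dth <- stats::rnorm(nf, 0, 0.03)
      for (i in 2:nf) {
        th[i] <- th[i - 1] + if (v_cmd[i - 1] > 0) dth[i] else 0
        step <- v_cmd[i - 1] / fr
        p <- xy[i - 1, ] + step * c(cos(th[i]), sin(th[i]))
        # reflect off the walls
        for (k in 1:2) {
          if (p[k] < margin || p[k] > cfg$arena_mm - margin) {
            th[i] <- if (k == 1) pi - th[i] else -th[i]
            p <- xy[i - 1, ] + step * c(cos(th[i]), sin(th[i]))
          }
        }
        xy[i, ] <- p
      }
    } else {
      xy <- matrix(rep(cfg$arena_mm / 2, 2 * nf), nf, 2)
      th <- rep(0, nf) # facing +x
    }

    # ---- substrate -------------------------------------------------------
    surface <- list()
    wheel <- NULL
    if (cfg$task == "TRM") {
      belt_pos <- cumsum(v_cmd) / fr # mm of belt travel
      belt_len <- 800
      view <- c(0, 300)
      for (k in 1:4) {
        ck <- (200 * (k - 1) - belt_pos) %% belt_len
        vis <- ck >= view[1] & ck <= view[2]
        m <- cbind(ck - 150, rep(-60, nf), rep(0, nf))
        m[!vis, ] <- NA_real_
        surface[[paste0("belt_", k)]] <- trajectory(m)
      }
    } else if (cfg$task == "CLB") {
      r <- 125
      c0 <- c(cfg$arena_mm / 2, 80, 135)
      omega <- v_cmd / r # rad/s, wheel surface matches climbing speed
      theta <- cumsum(omega) / fr
      for (k in 1:8) {
        a <- 2 * pi * (k - 1) / 8 + theta
        m <- cbind(c0[1] + r * cos(a), rep(c0[2], nf), c0[3] + r * sin(a))
        surface[[paste0("rim_", k)]] <- trajectory(m)
      }
      wheel <- list(center = c0, radius = r, theta = theta)
    }

    # ---- gait ------------------------------------------------------------
    # per-ankle along-heading progression g(t) and vertical arc dz(t)
    gait <- list(
      ankle_L = list(g = numeric(nf), dz = numeric(nf)),
      ankle_R = list(g = numeric(nf), dz = numeric(nf))
    )
    swings <- list(
      ankle_L = data.frame(start = integer(), end = integer(), peak_frame = integer()),
      ankle_R = data.frame(start = integer(), end = integer(), peak_frame = integer())
    )
    P <- 1 / gm$stride_hz
    if (cfg$task == "TRM" && em$speed_mm_s > 0) {
      # continuous cycles: swing = one full period between vertical minima;
      # phase-shifted so the first and last troughs fall in the interior
      d_v <- 0.4 * P
      for (leg in c("ankle_L", "ankle_R")) {
        ph <- if (leg == "ankle_L") 0.3 * P else 0.8 * P
        gait[[leg]]$dz <- gm$swing_height_mm / 2 * (1 - cos(2 * pi * (t - ph) / P))
        ks <- 0:floor((cfg$duration_s - ph) / P)
        cyc_start <- ph + ks * P
        cyc_start <- cyc_start[cyc_start + P <= cfg$duration_s + 1e-9]
        peak_t <- cyc_start + P / 2
        vg <- numeric(nf)
        for (cs in cyc_start) {
          vg <- vg + cos2_pulse(t, cs + P / 2 + gm$peak_speed_offset_s, d_v)
        }
        vg <- vg * em$speed_mm_s * P # each pulse displaces one step length
        gait[[leg]]$g <- cumsum(vg - v_cmd) / fr
        swings[[leg]] <- data.frame(
          start = as.integer(round(cyc_start * fr)),
          end = as.integer(round((cyc_start + P) * fr)),
          peak_frame = as.integer(round(peak_t * fr))
        )
      }
    } else if (cfg$task == "OF" && !is.null(walk_windows)) {
      d <- gm$swing_duration_s
      d_v <- 0.5 * d
      for (leg in c("ankle_L", "ankle_R")) {
        ph <- if (leg == "ankle_L") 0 else 0.5 * P
        st <- en <- pk <- numeric(0)
        vg <- dz <- numeric(nf)
        for (i in seq_len(nrow(walk_windows))) {
          s0 <- walk_windows$start[i] + 0.1 + ph
          while (s0 + d <= walk_windows$end[i] - 0.05) {
            u <- (t - s0) / d
            inswing <- u >= 0 & u < 1
            dz[inswing] <- dz[inswing] +
              gm$swing_height_mm / 2 * (1 - cos(2 * pi * u[inswing]))
            vg <- vg + em$speed_mm_s * P *
              cos2_pulse(t, s0 + d / 2 + gm$peak_speed_offset_s, d_v)
            st <- c(st, s0)
            en <- c(en, s0 + d)
            pk <- c(pk, s0 + d / 2)
            s0 <- s0 + P
          }
        }
        gait[[leg]]$dz <- dz
        gait[[leg]]$g <- cumsum(vg - v_cmd) / fr
        swings[[leg]] <- data.frame(
          start = as.integer(round(st * fr)),
          end = as.integer(round(en * fr)),
          peak_frame = as.integer(round(pk * fr))
        )
      }
    }

    # ---- assemble clean markers -----------------------------------------
    fwd <- cbind(cos(th), sin(th))
    lat <- cbind(-sin(th), cos(th))
    markers <- stats::setNames(vector("list", nrow(lay)), lay$label)
    tm <- cfg$tremor_model
    bm <- cfg$breathing_model
    amp_of <- function(model_amp, label) {
      if (!is.null(names(model_amp))) {
        as.numeric(model_amp[[label]] %||% 0)
      } else {
        as.numeric(model_amp)
      }
    }
    tremor_truth <- NULL
    if (isTRUE(tm$on)) {
      tremor_truth <- list(
        frequency_hz = tm$frequency_hz,
        amplitude_mm = stats::setNames(
          vapply(lay$label, function(l) amp_of(tm$amplitude_mm, l), numeric(1)),
          lay$label
        ),
        phase_rad = stats::setNames(
          vapply(lay$label, function(l) amp_of(tm$phase_rad, l), numeric(1)),
          lay$label
        )
      )
    }
    breath_phase <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(nrow(lay))) {
      lab <- lay$label[i]
      base_xy <- xy + fwd * lay$fwd[i] + lat * lay$lat[i]
      z <- rep(lay$z[i], nf)
      if (lab %in% names(gait)) {
        base_xy <- base_xy + fwd * gait[[lab]]$g
        z <- z + gait[[lab]]$dz
      }
      m <- cbind(base_xy, z)
      if (isTRUE(tm$on)) {
        a <- tremor_truth$amplitude_mm[[lab]]
        phi <- tremor_truth$phase_rad[[lab]]
        osc <- sin(2 * pi * tm$frequency_hz * t + phi)
        m <- m + a * cbind(osc, osc, 0.8 * osc)
      }
      if (isTRUE(bm$on) && grepl("^shoulder", lab)) {
        m[, 3] <- m[, 3] +
          bm$amplitude_mm * sin(2 * pi * bm$frequency_hz * t + breath_phase)
      }
      markers[[lab]] <- trajectory(m)
    }

    pairs <- marker_pairs(
      lay$label[seq(1, 9, by = 2)], lay$label[seq(2, 10, by = 2)],
      rep(14, 5)
    )
    clean <- trial_recording(
      trial_id = sprintf("synthetic-seed%d", cfg$seed), task = cfg$task,
      markers = markers, frame_rate = fr, surface_markers = surface,
      known_pairs = pairs
    )

    # ---- ground-truth measurements on the clean trial -------------------
    hip_clean <- hip_midpoint(clean)
    ref_clean <- if (cfg$task == "TRM") {
      # motion relative to the belt: add back the belt travel along x
      m <- unclass(hip_clean)
      m[, 1] <- m[, 1] + cumsum(v_cmd) / fr
      as_trajectory(m)
    } else if (cfg$task == "CLB") {
      m <- unclass(hip_clean)
      rel <- rotate_about_axis(
        m, wheel$center, c(0, 1, 0), -wheel$theta
      )
      as_trajectory(rel)
    } else {
      hip_clean
    }
    sp_clean <- windowed_speed(ref_clean, 100, fr)
    episodes <- detect_locomotion_episodes(sp_clean)

    measure_swings <- function(leg) {
      sw <- swings[[leg]]
      if (!nrow(sw)) {
        return(cbind(sw, duration_s = numeric(0), height_mm = numeric(0),
                     distance_mm = numeric(0)))
      }
      m <- unclass(markers[[leg]])
      sw$duration_s <- (sw$end - sw$start) / fr
      sw$height_mm <- vapply(seq_len(nrow(sw)), function(k) {
        zz <- m[interval_rows(sw$start[k], sw$end[k]), 3]
        max(zz) - min(zz)
      }, numeric(1))
      sw$distance_mm <- vapply(seq_len(nrow(sw)), function(k) {
        rows <- interval_rows(sw$start[k], sw$end[k])
        sqrt(sum((m[rows[length(rows)], ] - m[rows[1], ])^2))
      }, numeric(1))
      sw
    }
    truth <- list(
      episodes = episodes[, c("start", "end")],
      swings = list(
        ankle_L = measure_swings("ankle_L"),
        ankle_R = measure_swings("ankle_R")
      ),
      tremor = tremor_truth,
      gaps = data.frame(),
      glitches = data.frame(),
      clean = clean,
      body_speed = sp_clean
    )

    # ---- noise and degradation ------------------------------------------
    trial <- clean
    if (cfg$noise_sd > 0) {
      for (lab in names(trial$markers)) {
        m <- unclass(trial$markers[[lab]])
        trial$markers[[lab]] <- trajectory(
          m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
        )
      }
      for (lab in names(trial$surface_markers)) {
        m <- unclass(trial$surface_markers[[lab]])
        trial$surface_markers[[lab]] <- trajectory(
          m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
        )
      }
    }
    if (cfg$gap_model$rate_per_marker_min > 0 ||
        cfg$glitch_model$rate_per_marker_min > 0) {
      sub_seed <- sample.int(.Machine$integer.max, 1)
      deg <- degrade_trial(trial, cfg$gap_model, cfg$glitch_model, sub_seed)
      trial <- deg$trial
      truth$gaps <- deg$gaps
      truth$glitches <- deg$glitches
    }
    structure(list(trial = trial, truth = truth), class = "synthetic_trial")
  })
}

#' Inject occlusion gaps and short glitches into a trial
#'
#' Returns both the degraded trial and the exact list of injected events, so
#' the injected set can serve as ground truth for gap/glitch detection.
#' Events are placed by rejection sampling so they never overlap each other,
#' the trial boundaries, or existing missing data; if an event cannot be
#' placed the function errors rather than silently truncating.
#'
#' @param trial a [trial_recording()].
#' @param gap_model list: `rate_per_marker_min`, `mean_duration_frames`.
#' @param glitch_model list: `rate_per_marker_min`, `amplitude_mm`,
#'   `max_width_frames`.
#' @param seed integer RNG seed.
#' @return list with `trial`, `gaps` (marker, start, end, duration_frames),
#'   `glitches` (marker, axis, frame, width_frames, amplitude_mm).
#' @export
degrade_trial <- function(trial, gap_model = list(), glitch_model = list(),
                          seed = 1L) {
  gap_model <- utils::modifyList(
    list(rate_per_marker_min = 0, mean_duration_frames = 20), gap_model
  )
  glitch_model <- utils::modifyList(
    list(rate_per_marker_min = 0, amplitude_mm = 0.1, max_width_frames = 3),
    glitch_model
  )
  stopifnot(
    gap_model$rate_per_marker_min >= 0,
    glitch_model$rate_per_marker_min >= 0,
    glitch_model$max_width_frames <= 3
  )
  with_seed(seed, {
    nf <- trial_frames(trial)
    minutes <- nf / trial$frame_rate / 60
    gaps <- list()
    glitches <- list()
    for (lab in names(trial$markers)) {
      m <- unclass(trial$markers[[lab]])
      blocked <- traj_missing(trial$markers[[lab]])
      place <- function(width, pad) {
        for (try in 1:1000) {
          s <- sample.int(nf - width - 2 * pad, 1) + pad # 1-based start row
          span <- max(1L, s - pad):min(nf, s + width - 1L + pad)
          if (!any(blocked[span])) {
            return(s)
          }
        }
        stop("could not place a degradation event without overlap")
      }
      n_gap <- stats::rpois(1, gap_model$rate_per_marker_min * minutes)
      if (n_gap > 0) {
        for (i in seq_len(n_gap)) {
          dur <- 1L + stats::rgeom(1, 1 / gap_model$mean_duration_frames)
          dur <- min(dur, nf - 20L)
          s <- place(dur, 3L)
          m[s:(s + dur - 1L), ] <- NA_real_
          blocked[max(1L, s - 3L):min(nf, s + dur + 2L)] <- TRUE
          gaps[[length(gaps) + 1]] <- data.frame(
            marker = lab, start = s - 1L, end = s + dur - 1L,
            duration_frames = dur, stringsAsFactors = FALSE
          )
        }
      }
      n_gl <- stats::rpois(1, glitch_model$rate_per_marker_min * minutes)
      if (n_gl > 0) {
        for (i in seq_len(n_gl)) {
          w <- sample.int(glitch_model$max_width_frames, 1)
          s <- place(w, 6L)
          ax <- sample.int(3, 1)
          amp <- glitch_model$amplitude_mm * sample(c(-1, 1), 1)
          m[s:(s + w - 1L), ax] <- m[s:(s + w - 1L), ax] + amp
          blocked[max(1L, s - 6L):min(nf, s + w + 5L)] <- TRUE
          glitches[[length(glitches) + 1]] <- data.frame(
            marker = lab, axis = c("x", "y", "z")[ax], frame = s - 1L,
            width_frames = w, amplitude_mm = amp, stringsAsFactors = FALSE
          )
        }
      }
      trial$markers[[lab]] <- trajectory(m)
    }
    list(
      trial = trial,
      gaps = if (length(gaps)) do.call(rbind, gaps) else data.frame(),
      glitches = if (length(glitches)) do.call(rbind, glitches) else data.frame()
    )
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  print(x$trial)
  cat(sprintf(
    "  truth: %d episodes, %d+%d swings (L+R), %d gaps, %d glitches, tremor %s\n",
    nrow(x$truth$episodes),
    nrow(x$truth$swings$ankle_L), nrow(x$truth$swings$ankle_R),
    NROW(x$truth$gaps), NROW(x$truth$glitches),
    if (is.null(x$truth$tremor)) "off" else sprintf("%g Hz", x$truth$tremor$frequency_hz)
  ))
  invisible(x)
}
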