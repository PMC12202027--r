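# Reference point, windowed speed, episode segmentation, surface-relative
# motion, head orientation.

test_that("hip midpoint is the arithmetic midpoint with missing propagation", {
  n <- 10
  a <- matrix(rep(c(0, 0, 0), each = n), n, 3)
  b <- matrix(rep(c(2, 0, 0), each = n), n, 3)
  a[4, ] <- NA
  tr <- trial_recording("h", "OF",
    markers = list(hip_L = trajectory(a), hip_R = trajectory(b))
  )
  mid <- hip_midpoint(tr)
  expect_equal(unclass(mid)[1, ], c(x = 1, y = 0, z = 0))
  expect_true(traj_missing(mid)[4])
  expect_error(hip_midpoint(tiny_trial(5)), "hip markers not found")
})

test_that("midpoint of a rigid pair is equidistant at half the known distance", {
  set.seed(3)
  n <- 50
  a <- random_traj(n, 7)
  offs <- c(14, 0, 0)
  b <- trajectory(unclass(a) + matrix(rep(offs, each = n), n, 3))
  tr <- trial_recording("g", "OF", markers = list(hip_L = a, hip_R = b))
  mid <- unclass(hip_midpoint(tr))
  da <- sqrt(rowSums((mid - unclass(a))^2))
  db <- sqrt(rowSums((mid - unclass(b))^2))
  expect_equal(da, db, tolerance = 1e-12)
  expect_equal(da, rep(7, n), tolerance = 1e-12)
})

test_that("windowed speed matches the endpoint-displacement definition", {
  fr <- 300
  n <- 600
  expect_equal(max(as.numeric(windowed_speed(flat_traj(n), 100, fr)), na.rm = TRUE), 0)
  v <- as.numeric(windowed_speed(line_traj(n, 60, fr), 50, fr))
  expect_equal(v[is.finite(v)], rep(60, sum(is.finite(v))), tolerance = 1e-9)
  # sinusoidal path against a brute-force oracle
  t <- (seq_len(n) - 1) / fr
  m <- cbind(30 * sin(2 * pi * t), 10 * cos(2 * pi * 0.5 * t), 15 + 0 * t)
  w <- 40L
  got <- as.numeric(windowed_speed(trajectory(m), w, fr))
  h1 <- w %/% 2L
  h2 <- w - h1
  for (i in c(h1 + 1, 100, 300, n - h2)) {
    expect_equal(got[i], sqrt(sum((m[i + h2, ] - m[i - h1, ])^2)) * fr / w)
  }
  expect_true(all(is.na(got[c(1:h1, (n - h2 + 1):n)])))
  # missing endpoints leave the frame undefined
  mm <- m
  mm[200, ] <- NA
  gna <- as.numeric(windowed_speed(trajectory(mm), w, fr))
  expect_true(is.na(gna[200 - h2]) && is.na(gna[200 + h1]))
})

# independent oracle: iterative pairwise merging to a fixed point
oracle_episodes <- function(v, thr = 40, min_frames = 100, max_dip = 50) {
  above <- !is.na(v) & v > thr
  segs <- NULL
  r <- rle(above)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1
  segs <- cbind(s[r$values], e[r$values])
  if (is.null(segs) || nrow(segs) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  repeat {
    merged <- FALSE
    if (nrow(segs) > 1) {
      for (i in seq_len(nrow(segs) - 1)) {
        if (segs[i + 1, 1] - segs[i, 2] - 1 <= max_dip) {
          segs[i, 2] <- segs[i + 1, 2]
          segs <- segs[-(i + 1), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- segs[, 2] - segs[, 1] + 1 >= min_frames
  data.frame(start = segs[keep, 1] - 1L, end = segs[keep, 2])
}

test_that("episode detection handles the printed threshold cases", {
  expect_identical(nrow(detect_locomotion_episodes(rep(0, 1000))), 0L)
  ep <- detect_locomotion_episodes(c(rep(0, 50), rep(50, 150), rep(0, 50)))
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$duration_frames, 150L)
  # dip of 40 frames joins two 80-frame runs into one 200-frame episode
  v <- c(rep(0, 30), rep(50, 80), rep(30, 40), rep(50, 80), rep(0, 30))
  ep2 <- detect_locomotion_episodes(v)
  expect_identical(nrow(ep2), 1L)
  expect_identical(ep2$duration_frames, 200L)
  expect_identical(ep2$start, 30L)
  expect_identical(ep2$end, 230L)
  # a 51-frame dip splits it and neither half reaches 100 frames
  v3 <- c(rep(0, 30), rep(50, 80), rep(30, 51), rep(50, 80), rep(0, 30))
  expect_identical(nrow(detect_locomotion_episodes(v3)), 0L)
})

test_that("episode detection equals the merging oracle on random traces", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(200:2000, 1)
    # block-structured speeds so runs of realistic lengths appear
    nblk <- max(2, round(n / sample(20:100, 1)))
    v <- rep(runif(nblk, 0, 90), length.out = n)
    v <- v[order(rep(seq_len(nblk), length.out = n))]
    got <- detect_locomotion_episodes(v)
    want <- oracle_episodes(v)
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
  }
})

test_that("episodes are disjoint, sorted, edge-trimmed and stable under edge padding", {
  set.seed(99)
  v <- rep(runif(40, 0, 80), each = 30)
  ep <- detect_locomotion_episodes(v)
  if (nrow(ep) > 1) {
    expect_true(all(diff(ep$start) > 0))
    expect_true(all(ep$start[-1] >= ep$end[-nrow(ep)]))
  }
  for (i in seq_len(nrow(ep))) {
    expect_gt(v[ep$start[i] + 1], 40) # first frame supra-threshold
    expect_gt(v[ep$end[i]], 40) # last frame supra-threshold
  }
  ep_pad <- detect_locomotion_episodes(c(rep(0, 25), v, rep(0, 25)))
  expect_equal(ep_pad$start, ep$start + 25L)
  expect_equal(ep_pad$end, ep$end + 25L)
})

test_that("whole-trial locomotion summary follows plain kinematics", {
  fr <- 300
  n <- 60 * fr
  tr <- line_traj(n, 50, fr)
  sp <- windowed_speed(tr, 100, fr)
  ep <- detect_locomotion_episodes(sp)
  s <- trial_locomotion_summary(tr, ep, sp, fr)
  expect_equal(s$distance_mm, 50 * (n - 1) / fr, tolerance = 1e-6)
  expect_equal(s$time_locomoting_s, (n - 100) / fr, tolerance = 0.01)
  expect_equal(s$mean_locomotory_speed, 50, tolerance = 1e-6)
  expect_equal(nrow(s$binned), 60 / 10)
  # static trial: zero distance, no locomotion, undefined mean speed
  s0 <- trial_locomotion_summary(
    flat_traj(n),
    detect_locomotion_episodes(rep(0, n)), NULL, fr
  )
  expect_equal(s0$distance_mm, 0)
  expect_equal(s0$time_locomoting_s, 0)
  expect_true(is.na(s0$mean_locomotory_speed))
})

belt_trial <- function(mouse_speed, belt_speed, n = 3000, fr = 300) {
  t <- (seq_len(n) - 1) / fr
  belt_pos <- belt_speed * t
  surface <- list()
  for (k in 1:4) {
    ck <- (200 * (k - 1) - belt_pos) %% 800
    vis <- ck <= 300
    m <- cbind(ck - 150, rep(-60, n), rep(0, n))
    m[!vis, ] <- NA
    surface[[paste0("belt_", k)]] <- trajectory(m)
  }
  mk <- function(off) line_traj(n, mouse_speed, fr, origin = c(off, 0, 25))
  trial_recording("belt", "TRM",
    markers = list(hip_L = mk(0), hip_R = mk(14)),
    surface_markers = surface, frame_rate = fr
  )
}

test_that("belt correction recovers motion relative to the treadmill", {
  fr <- 300
  # stationary mouse on a belt moving at 150 mm/s: relative speed 150
  tr <- surface_relative(belt_trial(0, 150))
  sp <- as.numeric(windowed_speed(hip_midpoint(tr), 100, fr))
  expect_equal(median(sp, na.rm = TRUE), 150, tolerance = 1)
  # mouse matching the belt: relative speed 0
  tr2 <- surface_relative(belt_trial(-150, 150))
  sp2 <- as.numeric(windowed_speed(hip_midpoint(tr2), 100, fr))
  expect_lt(median(abs(sp2), na.rm = TRUE), 1)
})

test_that("zero surface motion leaves a trial unchanged (belt and wheel)", {
  n <- 600
  fr <- 300
  surface <- list(
    belt_1 = flat_traj(n, x = -100, y = -60),
    belt_2 = flat_traj(n, x = 100, y = -60)
  )
  body <- random_traj(n, 17)
  tr <- trial_recording("idb", "TRM",
    markers = list(hip_L = body), surface_markers = surface, frame_rate = fr
  )
  rel <- surface_relative(tr)
  expect_equal(unclass(rel$markers$hip_L), unclass(body),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # static wheel
  ang <- 2 * pi * (0:7) / 8
  rim <- setNames(lapply(ang, function(a) {
    flat_traj(n, x = 150 + 125 * cos(a), y = 80, z = 135 + 125 * sin(a))
  }), paste0("rim_", 1:8))
  trw <- trial_recording("idw", "CLB",
    markers = list(hip_L = body), surface_markers = rim, frame_rate = fr
  )
  relw <- surface_relative(trw)
  expect_equal(unclass(relw$markers$hip_L), unclass(body),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("wheel rotation with a lab-fixed mouse gives tangential speed omega*r", {
  n <- 1500
  fr <- 300
  omega <- 1.2 # rad/s
  t <- (seq_len(n) - 1) / fr
  c0 <- c(150, 80, 135)
  r <- 125
  rim <- setNames(lapply(0:7, function(k) {
    a <- 2 * pi * k / 8 + omega * t
    trajectory(cbind(c0[1] + r * cos(a), rep(c0[2], n), c0[3] + r * sin(a)))
  }), paste0("rim_", 1:8))
  # mouse fixed in the lab at radius rho from the wheel axis
  p <- c(c0[1] + 80, c0[2] - 10, c0[3] - 60)
  rho <- sqrt(80^2 + 60^2)
  tr <- trial_recording("w", "CLB",
    markers = list(hip_L = flat_traj(n, p[1], p[2], p[3])),
    surface_markers = rim, frame_rate = fr
  )
  rel <- surface_relative(tr)
  sp <- as.numeric(windowed_speed(rel$markers$hip_L, 30, fr))
  expect_equal(median(sp, na.rm = TRUE), omega * rho, tolerance = 0.02 * omega * rho)
  # distance from the fitted axis is preserved
  model <- attr(rel, "surface_model")
  expect_equal(model$radius, r, tolerance = 0.5)
})

headplate <- function(n = 5) {
  list(
    fl = flat_traj(n, 12, 8, 0), fr_ = flat_traj(n, 12, -8, 0),
    bl = flat_traj(n, -12, 8, 0), br = flat_traj(n, -12, -8, 0)
  )
}

test_that("a horizontal forward-facing plate reads yaw/pitch/roll zero", {
  hp <- headplate()
  pose <- head_orientation(hp, front_labels = c("fl", "fr_"), back_labels = c("bl", "br"))
  expect_equal(unname(unlist(pose$angles[1, ])), c(0, 0, 0), tolerance = 1e-9)
})

test_that("pure rotations are recovered as the matching Euler angles", {
  hp <- headplate()
  rotz <- function(d) {
    a <- d * pi / 180
    rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  }
  roty <- function(d) {
    a <- d * pi / 180
    rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  }
  rotx <- function(d) {
    a <- d * pi / 180
    rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  }
  apply_R <- function(mks, R) lapply(mks, function(m) trajectory(unclass(m) %*% t(R)))
  pose_of <- function(mks) {
    head_orientation(mks, front_labels = c("fl", "fr_"), back_labels = c("bl", "br"))$angles[1, ]
  }
  p_yaw <- pose_of(apply_R(hp, rotz(90)))
  expect_equal(unname(unlist(p_yaw)), c(90, 0, 0), tolerance = 1e-6)
  # pitch convention: positive pitch = nose up (rotation by -30 deg about y)
  p_pitch <- pose_of(apply_R(hp, roty(-30)))
  expect_equal(unname(unlist(p_pitch)), c(0, 30, 0), tolerance = 1e-6)
  p_roll <- pose_of(apply_R(hp, rotx(20)))
  expect_equal(unname(unlist(p_roll)), c(0, 0, 20), tolerance = 1e-6)
  # random combined rotations round-trip through the z-y'-x'' composition
  set.seed(8)
  for (k in 1:10) {
    y <- runif(1, -170, 170)
    p <- runif(1, -60, 60)
    r <- runif(1, -60, 60)
    R <- rotz(y) %*% roty(-p) %*% rotx(r)
    got <- pose_of(apply_R(hp, R))
    expect_equal(unname(unlist(got)), c(y, p, r), tolerance = 1e-6)
  }
})

test_that("degenerate headplate frames are undefined", {
  hp <- headplate()
  hp$fl <- trajectory(matrix(NA_real_, 5, 3))
  hp$fr_ <- trajectory(matrix(NA_real_, 5, 3))
  pose <- head_orientation(hp, front_labels = c("fl", "fr_"), back_labels = c("bl", "br"))
  expect_true(all(is.na(pose$angles$yaw)))
  # collinear markers
  col <- list(
    fl = flat_traj(5, 0, 0, 0), fr_ = flat_traj(5, 1, 0, 0),
    bl = flat_traj(5, 2, 0, 0)
  )
  pose2 <- head_orientation(col, front_labels = c("fl", "fr_"), back_labels = "bl")
  expect_true(all(is.na(pose2$angles$yaw)))
})
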