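# Fixture builders shared across the suite. All fixtures are constructed
# in code; randomized cases always fix their seed.

# trajectory from explicit coordinate vectors (recycled to n frames)
flat_traj <- function(n, x = 0, y = 0, z = 0) {
  trajectory(cbind(rep_len(x, n), rep_len(y, n), rep_len(z, n)))
}

# uniform linear motion at `v` mm/s along `dir` (unit vector), fr fps
line_traj <- function(n, v, fr, dir = c(1, 0, 0), origin = c(0, 0, 0)) {
  t <- (seq_len(n) - 1) / fr
  trajectory(cbind(
    origin[1] + v * t * dir[1],
    origin[2] + v * t * dir[2],
    origin[3] + v * t * dir[3]
  ))
}

# minimal two-marker trial
tiny_trial <- function(n = 5, task = "OF", fr = 300, ...) {
  trial_recording(
    trial_id = "tiny", task = task, frame_rate = fr,
    markers = list(M1 = flat_traj(n), M2 = flat_traj(n, x = 10)),
    ...
  )
}

# random walk trajectory with an optional missing mask
random_traj <- function(n, seed, step_sd = 0.5, missing_p = 0) {
  set.seed(seed)
  m <- apply(matrix(rnorm(3 * n, sd = step_sd), n, 3), 2, cumsum)
  if (missing_p > 0) {
    miss <- runif(n) < missing_p
    m[miss, ] <- NA_real_
  }
  trajectory(m)
}

# random trial for round-trip tests
random_trial <- function(seed, n = 20, n_markers = 3, residuals = FALSE) {
  set.seed(seed)
  labs <- paste0("m", seq_len(n_markers))
  markers <- setNames(
    lapply(seq_len(n_markers), function(i) random_traj(n, seed + i, missing_p = 0.1)),
    labs
  )
  trial_recording(
    trial_id = paste0("rt", seed), task = sample(c("OF", "CLB", "TRM"), 1),
    frame_rate = sample(c(100, 300), 1), markers = markers,
    known_pairs = marker_pairs(labs[1], labs[2], runif(1, 5, 30)),
    residuals = if (residuals) {
      setNames(lapply(labs, function(l) round(runif(n, 0.1, 0.6), 6)), labs)
    }
  )
}

expect_trials_equal <- function(a, b, tol = 1e-9) {
  expect_identical(a$trial_id, b$trial_id)
  expect_identical(a$task, b$task)
  expect_equal(a$frame_rate, b$frame_rate)
  expect_identical(sort(names(a$markers)), sort(names(b$markers)))
  for (lab in names(a$markers)) {
    expect_identical(traj_missing(a$markers[[lab]]), traj_missing(b$markers[[lab]]),
      info = paste("missing mask of", lab)
    )
    expect_equal(unclass(a$markers[[lab]]), unclass(b$markers[[lab]]),
      tolerance = tol, ignore_attr = TRUE
    )
  }
  if (!is.null(a$known_pairs)) {
    expect_equal(as.data.frame(a$known_pairs), as.data.frame(b$known_pairs),
      tolerance = tol, ignore_attr = TRUE
    )
  }
  if (!is.null(a$residuals)) {
    expect_equal(a$residuals, b$residuals, tolerance = tol)
  }
}
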