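# Spectral decomposition, tremor-band detection, Hilbert amplitude/phase,
# correlation matrices.

fr <- 300

test_that("a pure in-band sinusoid concentrates its analytic power at its frequency", {
  t <- (0:(10 * fr - 1)) / fr
  A <- 0.4
  x <- A * sin(2 * pi * 10 * t)
  ps <- power_spectrum(x, fr)
  expect_equal(ps$freq[which.max(ps$power)], 10, tolerance = ps$df + 1e-12)
  expect_equal(sum(ps$power) * ps$df, A^2 / 2, tolerance = 0.05 * A^2 / 2)
  # out-of-band sinusoid leaves almost nothing in 6-18 Hz
  x5 <- A * sin(2 * pi * 5 * t)
  ps5 <- power_spectrum(x5, fr)
  expect_lt(sum(ps5$power) * ps5$df, 0.01 * A^2 / 2)
})

test_that("white noise gives an approximately flat band spectrum", {
  set.seed(1)
  reps <- replicate(30, {
    ps <- power_spectrum(rnorm(10 * fr), fr)
    ps$power
  })
  m <- rowMeans(reps)
  expect_lt(stats::sd(m) / mean(m), 0.1)
})

test_that("spectrum smoothing is near-identity on smooth input and flat on flat input", {
  f <- seq(6, 18, by = 0.25)
  smooth_in <- structure(
    list(freq = f, power = exp(-(f - 11)^2 / 4), df = 0.25, band = c(6, 18)),
    class = "power_spectrum"
  )
  sm <- smooth_spectrum(smooth_in)
  expect_lt(max(abs(sm$power - smooth_in$power)), 0.01 * max(smooth_in$power))
  flat <- structure(
    list(freq = f, power = rep(2, length(f)), df = 0.25, band = c(6, 18)),
    class = "power_spectrum"
  )
  smf <- smooth_spectrum(flat)
  expect_lt(max(abs(smf$power - 2)), 1e-6)
  expect_error(smooth_spectrum(list(freq = 1:5, power = 1:5)), "8")
})

test_that("smoothing restores the argmax of a noisy unimodal spectrum", {
  f <- seq(6, 18, by = 0.25)
  clean <- exp(-(f - 11)^2 / 2)
  set.seed(3)
  hits <- vapply(1:20, function(i) {
    noisy <- structure(
      list(freq = f, power = pmax(clean + rnorm(length(f), 0, 0.08), 0),
           df = 0.25, band = c(6, 18)),
      class = "power_spectrum"
    )
    sm <- smooth_spectrum(noisy)
    abs(f[which.max(sm$power)] - f[which.max(clean)]) <= 0.25
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

# closed-form band boundaries for a Gaussian peak: |d/df exp(-(f-c)^2/2s^2)|
# falls back below 10% of its maximum at c +- x*s with x solving
# x*exp(-x^2/2) = 0.1 * exp(-1/2) on the outer flank
gaussian_band_halfwidth <- function(sigma) {
  g <- function(x) x * exp(-x^2 / 2) - 0.1 * exp(-0.5)
  sigma * uniroot(g, c(1, 6))$root
}

test_that("derivative band detection matches the Gaussian closed form", {
  f <- seq(6, 18, by = 0.05)
  sigma <- 1
  psd <- structure(
    list(freq = f, power = exp(-(f - 10)^2 / (2 * sigma^2)), df = 0.05,
         band = c(6, 18)),
    class = "power_spectrum"
  )
  bd <- find_tremor_band(psd)
  expect_identical(bd$strategy, 1L)
  expect_equal(bd$peak_frequency, 10, tolerance = 0.051)
  w <- gaussian_band_halfwidth(sigma)
  expect_equal(bd$band[1], 10 - w, tolerance = 0.11)
  expect_equal(bd$band[2], 10 + w, tolerance = 0.11)
  # symmetric within a bin
  expect_lt(abs((10 - bd$band[1]) - (bd$band[2] - 10)), 0.06)
})

test_that("flat and monotone spectra yield no band", {
  f <- seq(6, 18, by = 0.5)
  flat <- structure(list(freq = f, power = rep(1, length(f)), df = 0.5), class = "power_spectrum")
  expect_null(find_tremor_band(flat))
  mono <- structure(list(freq = f, power = f, df = 0.5), class = "power_spectrum")
  expect_null(find_tremor_band(mono))
})

test_that("the local-extrema fallback bounds a bimodal spectrum at the inter-peak minimum", {
  f <- seq(6, 18, by = 0.1)
  # broad dominant 12 Hz peak with a very steep 8 Hz satellite: the
  # satellite owns the maximum derivative, the broad flanks never reach 10%
  # of it, and the derivative walk fails
  p <- exp(-(f - 12)^2 / (2 * 1.5^2)) + 0.8 * exp(-(f - 8)^2 / (2 * 0.05^2))
  psd <- structure(list(freq = f, power = p, df = 0.1), class = "power_spectrum")
  bd <- find_tremor_band(psd)
  expect_identical(bd$strategy, 2L)
  expect_equal(bd$peak_frequency, 12, tolerance = 0.11)
  valley <- f[f > 8 & f < 12][which.min(p[f > 8 & f < 12])]
  expect_equal(bd$band[1], valley, tolerance = 0.11)
  expect_gt(bd$band[2], 12)
  # strategy 2 never fires on the standard smooth unimodal fixture
  g <- structure(list(freq = f, power = exp(-(f - 10)^2 / 2), df = 0.1), class = "power_spectrum")
  expect_identical(find_tremor_band(g)$strategy, 1L)
})

test_that("band-limited Hilbert recovers amplitude and phase of an in-band tone", {
  t <- (0:(10 * fr - 1)) / fr
  A <- 0.3
  f0 <- 10
  x <- A * sin(2 * pi * f0 * t)
  bh <- band_hilbert(x, c(8, 12), fr)
  core <- !bh$edge
  expect_equal(mean(bh$amplitude[core]), A, tolerance = 0.02 * A)
  expect_lt(max(abs(bh$amplitude[core] - A)), 0.05 * A)
  # phase advances at 2*pi*f0 rad/s
  dph <- diff(bh$phase[core])
  dph <- dph[abs(dph) < pi] # drop wraps
  expect_equal(median(dph) * fr, 2 * pi * f0, tolerance = 0.01 * 2 * pi * f0)
  expect_true(all(bh$phase > -pi - 1e-9 & bh$phase <= pi + 1e-9))
  # out-of-band tone is rejected
  x25 <- A * sin(2 * pi * 25 * t)
  bh25 <- band_hilbert(x25, c(8, 12), fr)
  expect_lt(mean(bh25$amplitude[!bh25$edge]), 0.02 * A)
  expect_error(band_hilbert(x, c(8, 200), fr), "Nyquist")
})

test_that("a slowly amplitude-modulated tone's envelope is tracked within 5%", {
  t <- (0:(20 * fr - 1)) / fr
  env <- 0.2 + 0.1 * sin(2 * pi * 0.2 * t)
  x <- env * sin(2 * pi * 10 * t)
  bh <- band_hilbert(x, c(7, 13), fr)
  core <- !bh$edge
  expect_lt(max(abs(bh$amplitude[core] - env[core]) / env[core]), 0.05)
})

test_that("windowed amplitude is an exact moving average", {
  a <- rep(2, 1000)
  wa <- windowed_amplitude(a, 150)
  expect_equal(wa[is.finite(wa)], rep(2, sum(is.finite(wa))))
  # step A -> 2A produces a ramp exactly one window wide
  stp <- c(rep(1, 500), rep(2, 500))
  ws <- windowed_amplitude(stp, 150)
  ramp <- which(is.finite(ws) & ws > 1 + 1e-12 & ws < 2 - 1e-12)
  expect_equal(length(ramp), 149)
  set.seed(2)
  r <- runif(400)
  got <- windowed_amplitude(r, 21)
  want <- vapply(1:400, function(i) {
    if (i - 10 < 1 || i + 10 > 400) NA_real_ else mean(r[(i - 10):(i + 10)])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

# O(n^2) pairwise definition of the Fisher-Lee coefficient
circ_corr_oracle <- function(a, b) {
  n <- length(a)
  num <- den_a <- den_b <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sin(a[i] - a[j]) * sin(b[i] - b[j])
      den_a <- den_a + sin(a[i] - a[j])^2
      den_b <- den_b + sin(b[i] - b[j])^2
    }
  }
  num / sqrt(den_a * den_b)
}

test_that("the O(n) circular correlation equals the pairwise definition", {
  set.seed(5)
  for (k in 1:5) {
    a <- runif(200, -pi, pi)
    b <- if (k %% 2) a + rnorm(200, 0, 0.3) else runif(200, -pi, pi)
    expect_equal(
      mocapkit:::circ_corr(a, b), circ_corr_oracle(a, b),
      tolerance = 1e-10
    )
  }
  # antiphase series: constant pi offset gives correlation +1
  a <- runif(300, -pi, pi)
  b <- ((a + pi + pi) %% (2 * pi)) - pi
  expect_equal(mocapkit:::circ_corr(a, b), 1, tolerance = 1e-10)
  expect_equal(circ_corr_oracle(a, b), 1, tolerance = 1e-10)
})

make_profile <- function(marker, axis, amp, phase, edge_n = 150) {
  n <- length(amp)
  edge <- rep(FALSE, n)
  edge[c(seq_len(edge_n), (n - edge_n + 1):n)] <- TRUE
  list(marker = marker, axis = axis, amplitude = amp, phase = phase, edge = edge)
}

test_that("correlation matrices behave on locked, independent and antiphase oscillators", {
  n <- 9000
  t <- (0:(n - 1)) / fr
  ph <- (2 * pi * 10 * t + pi) %% (2 * pi) - pi
  set.seed(7)
  amp1 <- 0.2 + 0.05 * sin(2 * pi * 0.1 * t)
  # identical phase-locked oscillators
  cm <- tremor_correlations(list(
    make_profile("a", "x", amp1, ph),
    make_profile("b", "x", amp1, ph)
  ))
  expect_equal(cm$amplitude_corr["a.x", "b.x"], 1, tolerance = 1e-9)
  expect_equal(cm$phase_corr["a.x", "b.x"], 1, tolerance = 1e-9)
  expect_equal(cm$amplitude_corr, t(cm$amplitude_corr))
  expect_equal(unname(diag(cm$phase_corr)), c(1, 1))
  # independent random amplitude envelopes decorrelate
  sm <- function(x) stats::filter(x, rep(1 / 11, 11), circular = TRUE)
  amp_a <- 0.2 + 0.05 * as.numeric(sm(rnorm(n)))
  amp_b <- 0.2 + 0.05 * as.numeric(sm(rnorm(n)))
  cm2 <- tremor_correlations(list(
    make_profile("a", "x", amp_a, ph),
    make_profile("b", "x", amp_b, ph)
  ))
  expect_lt(abs(cm2$amplitude_corr["a.x", "b.x"]), 0.1)
  # antiphase: magnitude 1, positive under the Fisher-Lee convention
  ph2 <- ((ph + pi + pi) %% (2 * pi)) - pi
  cm3 <- tremor_correlations(list(
    make_profile("a", "x", amp1, ph),
    make_profile("b", "x", amp1, ph2)
  ))
  expect_equal(abs(cm3$phase_corr["a.x", "b.x"]), 1, tolerance = 1e-6)
  # constant series are flagged undefined
  cm4 <- tremor_correlations(list(
    make_profile("a", "x", rep(0.2, n), ph),
    make_profile("b", "x", amp1, ph)
  ))
  expect_true(is.na(cm4$amplitude_corr["a.x", "b.x"]))
})

test_that("whole-trial tremor scan recovers injected frequency, amplitudes and phases", {
  amps <- c(
    shoulder_L = 0.2, shoulder_R = 0.2, lumbar_L = 0.2, lumbar_R = 0.2,
    hip_L = 0.4, hip_R = 0.2, knee_L = 0.2, knee_R = 0.2,
    ankle_L = 0.2, ankle_R = 0.2
  )
  phases <- c(
    shoulder_L = 0, shoulder_R = 0, lumbar_L = 0.4, lumbar_R = 0.4,
    hip_L = 0.8, hip_R = 0.8, knee_L = 1.2, knee_R = 1.2,
    ankle_L = 0, ankle_R = 0
  )
  st <- generate_trial(synthetic_config(
    seed = 41, duration_s = 30,
    episode_model = list(speed_mm_s = 0),
    tremor_model = list(on = TRUE, frequency_hz = 10, amplitude_mm = amps,
                        phase_rad = phases),
    breathing_model = list(on = FALSE), noise_sd = 0.01,
    gap_model = list(rate_per_marker_min = 0),
    glitch_model = list(rate_per_marker_min = 0)
  ))
  scan <- tremor_scan(st$trial, axes = "x")
  tb <- scan$table
  expect_true(all(is.finite(tb$peak_hz)))
  expect_true(all(abs(tb$peak_hz - 10) <= 0.5 + 1e-9)) # one spectral bin
  # x-axis analytic amplitude equals the injected per-marker amplitude
  expect_equal(tb$mean_amplitude_mm[tb$marker == "hip_L"], 0.4, tolerance = 0.02)
  expect_equal(tb$mean_amplitude_mm[tb$marker == "lumbar_L"], 0.2, tolerance = 0.01)
  # amplitude-doubled marker stands out ~2x
  expect_equal(
    tb$mean_amplitude_mm[tb$marker == "hip_L"] /
      tb$mean_amplitude_mm[tb$marker == "hip_R"], 2,
    tolerance = 0.05
  )
  # pairwise phase offsets recovered within 0.1 rad
  prof <- scan$profiles
  get_phase <- function(lab) prof[[which(vapply(prof, `[[`, "", "marker") == lab)]]$phase
  edge <- prof[[1]]$edge
  dphi <- function(a, b) {
    d <- get_phase(a)[!edge] - get_phase(b)[!edge]
    atan2(mean(sin(d)), mean(cos(d)))
  }
  expect_lt(abs(dphi("shoulder_L", "lumbar_L") - (0 - 0.4)), 0.1)
  expect_lt(abs(dphi("shoulder_L", "knee_L") - (0 - 1.2)), 0.1)
  # phase-locked whole body: strong positive phase correlations
  pc <- scan$correlations$phase_corr
  expect_gt(min(pc, na.rm = TRUE), 0.8)
})

test_that("a trial without tremor yields no band anywhere", {
  st <- generate_trial(synthetic_config(
    seed = 43, duration_s = 10,
    episode_model = list(speed_mm_s = 0),
    tremor_model = list(on = FALSE), breathing_model = list(on = FALSE),
    noise_sd = 0,
    gap_model = list(rate_per_marker_min = 0),
    glitch_model = list(rate_per_marker_min = 0)
  ))
  scan <- tremor_scan(st$trial)
  expect_true(all(is.na(scan$table$peak_hz)))
  expect_null(scan$correlations)
})

test_that("the scan is equivariant to marker order and axis relabeling", {
  st <- generate_trial(synthetic_config(
    seed = 47, duration_s = 10,
    episode_model = list(speed_mm_s = 0),
    tremor_model = list(on = TRUE, frequency_hz = 9),
    breathing_model = list(on = FALSE), noise_sd = 0.01,
    gap_model = list(rate_per_marker_min = 0),
    glitch_model = list(rate_per_marker_min = 0)
  ))
  s1 <- tremor_scan(st$trial, markers = c("hip_L", "knee_L"), axes = c("x", "z"))
  s2 <- tremor_scan(st$trial, markers = c("knee_L", "hip_L"), axes = c("z", "x"))
  t1 <- s1$table[order(s1$table$marker, s1$table$axis), ]
  t2 <- s2$table[order(s2$table$marker, s2$table$axis), ]
  expect_equal(t1$peak_hz, t2$peak_hz)
  expect_equal(t1$mean_amplitude_mm, t2$mean_amplitude_mm)
})
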