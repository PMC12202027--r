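# Tremor decomposition: band-limited power spectra, automatic tremor-band
# boundary detection, Hilbert amplitude/phase, windowed amplitude, and
# cross-marker/axis amplitude and phase correlation matrices.
#
# The analysis band is 6-18 Hz, bracketing the classic 8-12 Hz
# harmaline-tremor frequencies while excluding slow postural drift and
# breathing (~8 Hz oscillations sit inside the band on purpose: they are
# the smallest oscillation the method should still resolve).

#' Band-limited power spectral density of one marker axis
#'
#' Welch-averaged periodogram (Hann window, 2 s segments, 50% overlap)
#' restricted to the analysis band; each segment is mean-detrended before
#' the transform.
#'
#' @param x numeric signal (one axis of one marker, mm); must be gap-free.
#' @param frame_rate sampling rate (Hz).
#' @param band analysis band in Hz (default `c(6, 18)`).
#' @param seg_s Welch segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return object of class `power_spectrum`: list with `freq` (Hz),
#'   `power` (mm^2/Hz), `df` (bin width), `band`.
#' @export
power_spectrum <- function(x, frame_rate, band = c(6, 18), seg_s = 2,
                           overlap = 0.5) {
  if (anyNA(x)) stop("signal contains missing samples; fill gaps first")
  if (length(x) < 2 * frame_rate) stop("signal shorter than 2 s")
  ps <- welch_psd(x, frame_rate, seg_len = as.integer(seg_s * frame_rate),
                  overlap = overlap)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  structure(
    list(
      freq = ps$freq[sel], power = ps$power[sel],
      df = ps$freq[2] - ps$freq[1], band = band
    ),
    class = "power_spectrum"
  )
}

#' Smooth a power spectrum
#'
#' Smoothing-spline fit with the smoothing parameter selected automatically
#' by generalized cross-validation; output clipped at zero.
#'
#' @param psd a [power_spectrum()] (or list with `freq`, `power`).
#' @return the input with `power` replaced by the smoothed curve and the
#'   raw curve kept as `raw_power`.
#' @export
smooth_spectrum <- function(psd) {
  if (length(psd$freq) < 8) stop("need at least 8 frequency bins to smooth")
  fit <- stats::smooth.spline(psd$freq, psd$power, cv = FALSE)
  sm <- pmax(stats::predict(fit, psd$freq)$y, 0)
  out <- psd
  out$raw_power <- psd$power
  out$power <- sm
  out
}

#' Locate the tremor frequency band in a smoothed spectrum
#'
#' Two complementary strategies around the global spectral peak. Strategy
#' 1 (derivative analysis): walking outward from the peak, a boundary is
#' placed where the magnitude of the spectral derivative, having first
#' risen onto the peak's flank, falls below `deriv_frac` (10%) of its
#' maximum. Strategy 2 (fallback when strategy 1 yields an empty,
#' inverted, or sub-2-bin band): boundaries at the local minima flanking
#' the peak. A spectrum with no interior maximum yields no band.
#'
#' @param psd a smoothed [power_spectrum()].
#' @param deriv_frac derivative threshold as a fraction of the maximum
#'   absolute derivative (default 0.1).
#' @return list with `band` (c(low, high) Hz), `peak_frequency` (Hz) and
#'   `strategy` (1 or 2), or NULL when no band is found.
#' @export
find_tremor_band <- function(psd, deriv_frac = 0.1) {
  f <- psd$freq
  p <- psd$power
  n <- length(f)
  pk <- which.max(p)
  if (pk == 1L || pk == n) return(NULL) # monotone: no interior maximum
  d <- diff(p) / diff(f) # d[i] is the slope between bins i and i+1
  thr <- deriv_frac * max(abs(d))

  walk <- function(side) {
    # phase 1: leave the flat peak top (|d| rises to >= thr);
    # phase 2: continue until |d| drops back below thr
    if (side == "left") {
      j <- pk - 1L
      entered <- FALSE
      while (j >= 1L) {
        a <- abs(d[j])
        if (!entered && a >= thr) entered <- TRUE
        if (entered && a < thr) return(j + 1L)
        j <- j - 1L
      }
      if (entered) 1L else NA_integer_
    } else {
      j <- pk
      entered <- FALSE
      while (j <= n - 1L) {
        a <- abs(d[j])
        if (!entered && a >= thr) entered <- TRUE
        if (entered && a < thr) return(j)
        j <- j + 1L
      }
      if (entered) n else NA_integer_
    }
  }
  lo <- walk("left")
  hi <- walk("right")
  strategy <- 1L
  if (is.na(lo) || is.na(hi) || lo >= hi || (hi - lo) < 2L) {
    # strategy 2: nearest flanking local minima
    mins <- find_peaks(-p)$index
    left <- mins[mins < pk]
    right <- mins[mins > pk]
    lo <- if (length(left)) max(left) else 1L
    hi <- if (length(right)) min(right) else n
    strategy <- 2L
    if (lo >= hi || (hi - lo) < 2L) return(NULL)
  }
  list(band = c(f[lo], f[hi]), peak_frequency = f[pk], strategy = strategy)
}

#' Band-limited instantaneous amplitude and phase
#'
#' Zero-phase band-pass filtering (4th-order Butterworth applied
#' forward-backward) followed by the analytic signal; amplitude is its
#' modulus, phase its argument. Zero-phase filtering is required for the
#' phase series to be physically meaningful. The first and last 0.5 s are
#' flagged edge-unreliable.
#'
#' @param x numeric signal (mm), gap-free.
#' @param band c(low, high) Hz, inside (0, frame_rate / 2).
#' @param frame_rate sampling rate (Hz).
#' @return list with `amplitude` (mm), `phase` (rad, in (-pi, pi]),
#'   `filtered`, `edge` (logical edge-unreliable flag), `band`.
#' @export
band_hilbert <- function(x, band, frame_rate) {
  if (anyNA(x)) stop("signal contains missing samples; fill gaps first")
  nyq <- frame_rate / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("band must lie strictly inside (0, Nyquist)")
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  an <- analytic_signal(xf)
  n <- length(x)
  edge_n <- min(n, as.integer(round(0.5 * frame_rate)))
  edge <- rep(FALSE, n)
  edge[seq_len(edge_n)] <- TRUE
  edge[seq.int(n - edge_n + 1L, n)] <- TRUE
  list(
    amplitude = Mod(an), phase = Arg(an), filtered = xf,
    edge = edge, band = band
  )
}

#' Moving-average tremor amplitude
#'
#' @param amplitude instantaneous amplitude series (mm).
#' @param window_frames averaging window (default 150 frames, ~500 ms at
#'   300 fps).
#' @return numeric series; frames without a full window are NA.
#' @export
windowed_amplitude <- function(amplitude, window_frames = 150) {
  moving_average(amplitude, window_frames)
}

#' Cross-marker/axis amplitude and phase correlation matrices
#'
#' Amplitude correlations are Pearson correlations of the instantaneous
#' amplitude series; phase correlations are Fisher-Lee circular-circular
#' correlations of the instantaneous phases (linear correlation of wrapped
#' angles is ill-defined). Edge-unreliable frames are excluded. Entries
#' involving a constant series are NA.
#'
#' @param profiles list of tremor profiles, each a list with `marker`,
#'   `axis`, `amplitude`, `phase`, `edge` (as produced by [tremor_scan()]).
#' @return object of class `correlation_matrices`: `labels`,
#'   `amplitude_corr`, `phase_corr` (symmetric, unit diagonal).
#' @export
tremor_correlations <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  labs <- vapply(profiles, function(p) paste(p$marker, p$axis, sep = "."), "")
  keep <- !Reduce(`|`, lapply(profiles, function(p) p$edge))
  k <- length(profiles)
  ac <- pc <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(ac) <- diag(pc) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ai <- profiles[[i]]$amplitude[keep]
      aj <- profiles[[j]]$amplitude[keep]
      if (stats::sd(ai) > 0 && stats::sd(aj) > 0) {
        ac[i, j] <- ac[j, i] <- stats::cor(ai, aj)
      }
      pc[i, j] <- pc[j, i] <- circ_corr(
        profiles[[i]]$phase[keep], profiles[[j]]$phase[keep]
      )
    }
  }
  structure(
    list(labels = labs, amplitude_corr = ac, phase_corr = pc),
    class = "correlation_matrices"
  )
}

#' @export
print.correlation_matrices <- function(x, ...) {
  cat(sprintf("<correlation_matrices: %d marker-axis series>\n", length(x$labels)))
  cat("amplitude correlations:\n")
  print(round(x$amplitude_corr, 2))
  cat("phase correlations:\n")
  print(round(x$phase_corr, 2))
  invisible(x)
}

#' Tremor decomposition of a whole trial
#'
#' Runs the per-axis pipeline (band-limited PSD, spline smoothing, band
#' detection, band-limited Hilbert transform, windowed amplitude) for every
#' marker and axis on the longest stretch of frames where all included
#' markers are simultaneously observed, then assembles the cross-marker
#' correlation matrices from the marker-axis profiles with a detected band.
#'
#' @param trial a (cleaned) [trial_recording()].
#' @param markers labels to include (default: all body markers).
#' @param band analysis band in Hz (default `c(6, 18)`).
#' @param axes axes to analyze (default x, y, z).
#' @param seg_s Welch segment length (s).
#' @param deriv_frac band-detection derivative threshold (default 0.1).
#' @param amplitude_window_frames window for [windowed_amplitude()].
#' @return object of class `tremor_scan`: `profiles` (per marker-axis:
#'   band, peak frequency, amplitude/phase series, mean amplitude over
#'   non-edge frames, windowed amplitude), `table` (one row per
#'   marker-axis), `correlations`, `frames` (0-based interval analyzed).
#' @export
tremor_scan <- function(trial, markers = names(trial$markers),
                        band = c(6, 18), axes = c("x", "y", "z"),
                        seg_s = 2, deriv_frac = 0.1,
                        amplitude_window_frames = 150) {
  stopifnot(length(markers) >= 1)
  fr <- trial$frame_rate
  fin <- Reduce(`&`, lapply(trial$markers[markers], function(m) !traj_missing(m)))
  runs <- bool_runs(fin)
  runs <- runs[runs$value, , drop = FALSE]
  if (!nrow(runs)) stop("no frames where all requested markers are visible")
  best <- which.max(runs$end - runs$start)
  rows <- runs$start[best]:runs$end[best]
  if (length(rows) < 2 * fr) stop("common visible stretch shorter than 2 s")
  profiles <- list()
  tab <- list()
  for (lab in markers) {
    m <- unclass(trial$markers[[lab]])[rows, , drop = FALSE]
    for (ax in axes) {
      x <- m[, match(ax, c("x", "y", "z"))]
      ps <- smooth_spectrum(power_spectrum(x, fr, band = band, seg_s = seg_s))
      bd <- find_tremor_band(ps, deriv_frac = deriv_frac)
      row <- data.frame(
        marker = lab, axis = ax,
        band_low_hz = NA_real_, band_high_hz = NA_real_,
        peak_hz = NA_real_, mean_amplitude_mm = NA_real_,
        strategy = NA_integer_, stringsAsFactors = FALSE
      )
      if (!is.null(bd)) {
        bh <- band_hilbert(x, bd$band, fr)
        wa <- windowed_amplitude(bh$amplitude, amplitude_window_frames)
        row$band_low_hz <- bd$band[1]
        row$band_high_hz <- bd$band[2]
        row$peak_hz <- bd$peak_frequency
        row$mean_amplitude_mm <- mean(bh$amplitude[!bh$edge])
        row$strategy <- bd$strategy
        profiles[[length(profiles) + 1]] <- list(
          marker = lab, axis = ax, band = bd$band,
          peak_frequency = bd$peak_frequency,
          amplitude = bh$amplitude, phase = bh$phase, edge = bh$edge,
          windowed_amplitude = wa,
          mean_amplitude = row$mean_amplitude_mm
        )
      }
      tab[[length(tab) + 1]] <- row
    }
  }
  tab <- do.call(rbind, tab)
  corr <- if (length(profiles) >= 2) tremor_correlations(profiles)
  structure(
    list(
      profiles = profiles, table = tab, correlations = corr,
      frames = c(rows[1] - 1L, rows[length(rows)]), frame_rate = fr
    ),
    class = "tremor_scan"
  )
}

#' @export
print.tremor_scan <- function(x, ...) {
  found <- sum(!is.na(x$table$peak_hz))
  cat(sprintf(
    "<tremor_scan: frames [%d, %d), %d/%d marker-axis series with a tremor band>\n",
    x$frames[1], x$frames[2], found, nrow(x$table)
  ))
  if (found) {
    cat(sprintf(
      "  peak frequency %.1f-%.1f Hz, mean amplitude %.3f mm\n",
      min(x$table$peak_hz, na.rm = TRUE), max(x$table$peak_hz, na.rm = TRUE),
      mean(x$table$mean_amplitude_mm, na.rm = TRUE)
    ))
  }
  invisible(x)
}

#' @export
summary.tremor_scan <- function(object, ...) tremor_summary(object, ...)

#' Per-marker and per-axis tremor summaries
#'
#' Averages instantaneous amplitude across windows, axes and markers, and
#' splits tremor amplitude by movement state (reference-point speed above
#' vs below 10 mm/s).
#'
#' @param scan a [tremor_scan()].
#' @param speed optional full-trial reference speed series (mm/s) for the
#'   movement split.
#' @param move_threshold_mm_s movement split threshold (default 10 mm/s).
#' @return list with `per_marker` (peak Hz and mean amplitude),
#'   `per_axis_amplitude`, `amplitude_moving`, `amplitude_still`.
#' @export
tremor_summary <- function(scan, speed = NULL, move_threshold_mm_s = 10) {
  tb <- scan$table
  ok <- !is.na(tb$peak_hz)
  per_marker <- do.call(rbind, lapply(split(tb[ok, ], tb$marker[ok]), function(d) {
    data.frame(
      marker = d$marker[1], peak_hz = mean(d$peak_hz),
      mean_amplitude_mm = mean(d$mean_amplitude_mm)
    )
  }))
  per_axis <- tapply(tb$mean_amplitude_mm[ok], tb$axis[ok], mean)
  amp_mov <- amp_still <- NA_real_
  if (!is.null(speed) && length(scan$profiles)) {
    rows <- (scan$frames[1] + 1L):scan$frames[2]
    v <- as.numeric(speed)[rows]
    amp <- rowMeans(vapply(
      scan$profiles, function(p) p$amplitude,
      numeric(length(rows))
    ))
    edge <- scan$profiles[[1]]$edge
    mov <- !edge & is.finite(v) & v > move_threshold_mm_s
    still <- !edge & is.finite(v) & v <= move_threshold_mm_s
    if (any(mov)) amp_mov <- mean(amp[mov])
    if (any(still)) amp_still <- mean(amp[still])
  }
  list(
    per_marker = per_marker, per_axis_amplitude = per_axis,
    amplitude_moving_mm = amp_mov, amplitude_still_mm = amp_still
  )
}
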