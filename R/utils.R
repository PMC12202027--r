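# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average
#'
#' Frames without a full window are NA.
#' @param x numeric vector.
#' @param w window length in samples (>= 1).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, w) {
  stopifnot(w >= 1)
  if (w == 1) return(x)
  if (w > length(x)) return(rep(NA_real_, length(x)))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# Run-length encoding of a logical mask as 1-based inclusive [start, end] rows.
bool_runs <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end, value = r$values)
}

#' Local maxima with topographic prominence
#'
#' A peak's prominence is its height above the higher of the two lowest points
#' one must descend to before reaching higher ground (or a signal end) on each
#' side. NA samples split the signal; peaks are searched within contiguous
#' finite stretches.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence to keep a peak.
#' @param min_separation minimum index distance between kept peaks; when two
#'   are closer, the higher one wins.
#' @return data.frame with 1-based `index`, `value`, `prominence`.
#' @keywords internal
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  empty <- data.frame(index = integer(), value = numeric(), prominence = numeric())
  if (n < 3) return(empty)
  finite <- is.finite(x)
  cand <- which(finite & c(FALSE, diff(x) > 0) & c(x[-n] > x[-1], FALSE))
  # strict rise then fall; extend to plateaus: take plateau starts where the
  # next distinct value is lower and the previous distinct value is lower
  if (!length(cand)) {
    cand <- which(finite[-c(1L, n)] &
      x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
    cand <- cand[x[cand] > x[cand - 1L] | vapply(cand, function(i) {
      j <- i
      while (j > 1 && is.finite(x[j - 1]) && x[j - 1] == x[i]) j <- j - 1L
      j > 1 && is.finite(x[j - 1]) && x[j - 1] < x[i]
    }, logical(1))]
  }
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    v <- x[i]
    # walk left
    lmin <- v
    j <- i - 1L
    while (j >= 1 && is.finite(x[j]) && x[j] <= v) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    lbase <- if (j >= 1 && is.finite(x[j])) lmin else min(lmin, v) # edge: use lowest seen
    if (j >= 1 && !is.finite(x[j])) lbase <- lmin
    # walk right
    rmin <- v
    j <- i + 1L
    while (j <= n && is.finite(x[j]) && x[j] <= v) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    rbase <- rmin
    v - max(lbase, rbase)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  ord <- order(x[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  taken <- integer()
  for (k in ord) {
    if (!length(taken) || all(abs(cand[k] - taken) >= min_separation)) {
      sel[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  out <- data.frame(index = cand[sel], value = x[cand[sel]], prominence = prom[sel])
  out[order(out$index), , drop = FALSE]
}

#' Welch-averaged one-sided power spectral density
#'
#' Hann-windowed, mean-detrended segments with the stated overlap; density
#' scaling such that a sinusoid of amplitude A integrates (sum * df) to A^2/2.
#'
#' @param x numeric vector, no NAs.
#' @param fs sampling frequency (Hz).
#' @param seg_len segment length in samples.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `power` (units^2/Hz).
#' @keywords internal
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  scale <- 2 / (fs * sum(w^2))
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / length(starts) * scale
  # DC and Nyquist bins are not doubled
  p[1] <- p[1] / 2
  if (seg_len %% 2 == 0) p[nf] <- p[nf] / 2
  list(freq = (seq_len(nf) - 1) * fs / seg_len, power = p)
}

#' Analytic signal via FFT
#'
#' @param x real numeric vector, no NAs.
#' @return complex vector whose modulus is the instantaneous amplitude and
#'   whose argument is the instantaneous phase.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Fisher-Lee circular-circular correlation
#'
#' T-linear association between two angular series, computed with the O(n)
#' trigonometric-moment identity. Returns NA when either series has no
#' angular dispersion.
#'
#' @param a,b angles in radians.
#' @return correlation in `[-1, 1]`, or NA.
#' @keywords internal
circ_corr <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  A <- sum(cos(a) * cos(b))
  B <- sum(sin(a) * sin(b))
  C <- sum(cos(a) * sin(b))
  D <- sum(sin(a) * cos(b))
  E <- sum(cos(2 * a))
  F_ <- sum(sin(2 * a))
  G <- sum(cos(2 * b))
  H <- sum(sin(2 * b))
  den <- (n^2 - E^2 - F_^2) * (n^2 - G^2 - H^2)
  if (den <= 0) return(NA_real_)
  4 * (A * B - C * D) / sqrt(den)
}

# Linear interpolation across an excised 1-based index span [i0, i1],
# anchored at x[i0 - 1] and x[i1 + 1]; both anchors must be finite.
interp_span <- function(x, i0, i1) {
  xa <- x[i0 - 1L]
  xb <- x[i1 + 1L]
  k <- i1 - i0 + 2L
  x[i0:i1] <- xa + (xb - xa) * seq_len(i1 - i0 + 1L) / k
  x
}
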