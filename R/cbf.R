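# Ciliary beat frequency from linescan traces. The acquisition this targets
# scans a single confocal line perpendicular to the ciliary axis at high rate
# (e.g. 529 lines/s, 5000 cycles); beating cilia modulate the intensity at
# each line position quasi-sinusoidally, and the dominant spectral peak in a
# physiological band is read out as the beat frequency.

#' Construct a linescan trace
#'
#' @param samples numeric intensity-versus-time vector, at least 16 samples.
#' @param sampling_rate sampling rate in Hz (> 0); the reference acquisition
#'   runs at 529 Hz.
#' @param n_positions spatial samples per scanned line (metadata only).
#' @return A `linescan_trace` list.
#' @export
linescan_trace <- function(samples, sampling_rate = 529, n_positions = 1L) {
  if (!is.numeric(samples) || length(samples) < 16L) {
    stop("'samples' must be a numeric vector of at least 16 values")
  }
  if (any(!is.finite(samples))) stop("'samples' must be finite")
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  if (n_positions < 1L) stop("'n_positions' must be >= 1")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 n_positions = as.integer(n_positions)),
            class = "linescan_trace")
}

# Welch averaged periodogram: Hann window, 50% overlap. Returns freq (Hz)
# and power density (arbitrary units) for the one-sided spectrum.
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 2048L)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  acc <- numeric(nperseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    sp <- stats::fft(seg * win)
    acc <- acc + Mod(sp[seq_len(nperseg %/% 2L + 1L)])^2
  }
  acc <- acc / length(starts)
  list(freq = (0:(nperseg %/% 2L)) * fs / nperseg, power = acc,
       df = fs / nperseg)
}

#' Estimate ciliary beat frequency from a linescan trace
#'
#' The trace is mean-removed and linearly detrended, its Welch-averaged
#' periodogram (Hann window, 50% overlap) is computed, and the frequency is
#' the location of the largest spectral peak inside `band`, refined by
#' parabolic interpolation of the peak bin and its neighbors. A trace with
#' no dominant oscillation (the winning peak's share of non-DC power below
#' `power_floor`) is rejected rather than returning a spurious frequency.
#'
#' @param trace a [linescan_trace()].
#' @param band numeric `(f_lo, f_hi)` search band in Hz. The default
#'   (1, 60) Hz excludes DC drift while covering physiological ciliary
#'   beating; `f_hi` must be below the Nyquist frequency (never silently
#'   folded).
#' @param nperseg Welch segment length; default `min(N, 2048)`.
#' @param power_floor minimum `power_fraction` accepted (default 0.05).
#' @return A `cbf_estimate` list: `frequency` (Hz) and `power_fraction`
#'   (power within one bin of the peak over total non-DC power).
#' @export
estimate_cbf <- function(trace, band = c(1, 60), nperseg = NULL,
                         power_floor = 0.05) {
  stopifnot(inherits(trace, "linescan_trace"))
  fs <- trace$sampling_rate
  nyq <- fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L]) {
    stop("'band' must be (f_lo, f_hi) with 0 < f_lo < f_hi")
  }
  if (band[2L] >= nyq) {
    stop(sprintf("band upper edge %.3g Hz is at or above Nyquist (%.3g Hz)",
                 band[2L], nyq))
  }
  x <- trace$samples
  tt <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))  # linear detrend
  if (stats::sd(x) <= 1e-8 * max(abs(trace$samples), 1)) {
    stop("no dominant frequency: trace is constant or a pure drift")
  }
  ps <- welch_psd(x, fs, nperseg)
  nondc <- ps$freq > 0
  total <- sum(ps$power[nondc])
  inband <- which(ps$freq >= band[1L] & ps$freq <= band[2L])
  if (length(inband) == 0L) stop("band contains no frequency bin")
  if (total <= 0) stop("no dominant frequency: trace is constant")
  k <- inband[which.max(ps$power[inband])]
  peak_power <- sum(ps$power[max(k - 1L, 1L):min(k + 1L, length(ps$power))])
  pf <- peak_power / total
  if (pf < power_floor) {
    stop(sprintf(
      "no dominant frequency: peak power fraction %.3g below floor %.3g",
      pf, power_floor))
  }
  # parabolic refinement on log power of the peak bin and neighbors
  f <- ps$freq[k]
  if (k > 1L && k < length(ps$power)) {
    lp <- log(pmax(ps$power[(k - 1L):(k + 1L)], .Machine$double.xmin))
    denom <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (denom < 0) {
      delta <- 0.5 * (lp[1L] - lp[3L]) / denom
      f <- f + max(-0.5, min(0.5, delta)) * ps$df
    }
  }
  structure(list(frequency = f, power_fraction = pf),
            class = "cbf_estimate")
}

#' @export
print.cbf_estimate <- function(x, ...) {
  cat(sprintf("CBF estimate: %.3f Hz (peak power fraction %.3f)\n",
              x$frequency, x$power_fraction))
  invisible(x)
}

#' Peak-counting beat-frequency cross-check
#'
#' Counts upward zero crossings of the detrended trace and divides by the
#' duration. A coarse, window-free estimate used to sanity-check the
#' spectral value; sensitive to noise, so smooth first for low-SNR traces.
#'
#' @param trace a [linescan_trace()].
#' @return Frequency in Hz.
#' @export
count_beats <- function(trace) {
  stopifnot(inherits(trace, "linescan_trace"))
  x <- trace$samples - mean(trace$samples)
  up <- sum(x[-length(x)] < 0 & x[-1L] >= 0)
  up / (length(x) / trace$sampling_rate)
}

#' Build a kymograph along a line
#'
#' Samples the intensity of every frame at the given line points (bilinear
#' interpolation for sub-pixel coordinates), producing a position-by-time
#' map: row `i`, column `t` is the intensity at line point `i` in frame `t`.
#'
#' @param seq an [image_sequence()].
#' @param line numeric matrix (n x 2) of `(x, y)` pixel coordinates
#'   (0-based), all inside the frame.
#' @return Numeric matrix, `nrow(line)` rows by `n_frames(seq)` columns.
#' @export
kymograph <- function(seq, line) {
  stopifnot(inherits(seq, "image_sequence"))
  line <- matrix(as.numeric(line), ncol = 2L)
  d <- frame_dim(seq)
  if (any(line[, 1L] < 0 | line[, 1L] > d[2L] - 1 |
          line[, 2L] < 0 | line[, 2L] > d[1L] - 1)) {
    stop("line coordinates fall outside the frame")
  }
  out <- matrix(0, nrow(line), n_frames(seq))
  for (t in seq_len(n_frames(seq))) {
    out[, t] <- bilinear_sample(seq$frames[[t]], line[, 1L], line[, 2L])
  }
  out
}

# Bilinear interpolation at 0-based (x, y); clamps the upper edge so integer
# coordinates on the last row/column are exact.
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- pmax(pmin(floor(x), w - 2), 0)
  y0 <- pmax(pmin(floor(y), h - 2), 0)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  i1 <- pmin(i + 1, h); j1 <- pmin(j + 1, w)
  m[cbind(i, j)] * (1 - fx) * (1 - fy) +
    m[cbind(i, j1)] * fx * (1 - fy) +
    m[cbind(i1, j)] * (1 - fx) * fy +
    m[cbind(i1, j1)] * fx * fy
}
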