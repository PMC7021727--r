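# Physical flow summaries from tracks, and the two-group rank-sum comparison
# used to contrast bead-speed distributions between cohorts.

#' Mean speed of one track
#'
#' Speed is averaged over consecutive pairs of assigned samples: Euclidean
#' displacement in pixels times `pixel_size`, divided by the frame gap times
#' `frame_interval`. Coasted frames contribute no positions; a gap across a
#' coast enters through its larger frame difference (gap-aware denominator).
#'
#' @param track one element of a `bead_tracks` object (or any list with a
#'   `samples` data frame holding `frame`, `x`, `y`, `assigned`).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return Mean speed in micrometres per second.
#' @export
track_speed <- function(track, pixel_size, frame_interval) {
  s <- track$samples
  s <- s[s$assigned == 1L, , drop = FALSE]
  if (nrow(s) < 2L) stop("track speed is undefined for fewer than 2 samples")
  dx <- diff(s$x); dy <- diff(s$y); dt <- diff(s$frame)
  mean(sqrt(dx^2 + dy^2) * pixel_size / (dt * frame_interval))
}

#' Summarize flow over a cohort of tracks
#'
#' @param tracks a `bead_tracks` object from [track_sequence()].
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return A `flow_summary` list: `per_track_speed` (um/s, one per track),
#'   `mean_speed` (unweighted mean), `direction` (mean of per-track net
#'   displacement unit vectors; its norm is 1 for perfectly aligned flow and
#'   shrinks with directional dispersion), `n_tracks`.
#' @export
summarize_flow <- function(tracks, pixel_size, frame_interval) {
  ok <- Filter(function(tr) sum(tr$samples$assigned) >= 2L, tracks)
  if (length(ok) == 0L) stop("no track with at least 2 samples")
  speeds <- vapply(ok, track_speed, numeric(1),
                   pixel_size = pixel_size, frame_interval = frame_interval)
  units <- t(vapply(ok, function(tr) {
    s <- tr$samples[tr$samples$assigned == 1L, , drop = FALSE]
    v <- c(s$x[nrow(s)] - s$x[1L], s$y[nrow(s)] - s$y[1L])
    nv <- sqrt(sum(v^2))
    if (nv == 0) c(0, 0) else v / nv
  }, numeric(2)))
  structure(list(per_track_speed = speeds,
                 mean_speed = mean(speeds),
                 direction = colMeans(units),
                 n_tracks = length(ok)),
            class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf("flow_summary: %d tracks, mean speed %.3f um/s\n",
              x$n_tracks, x$mean_speed))
  cat(sprintf("  direction (%.3f, %.3f), |direction| = %.3f\n",
              x$direction[1L], x$direction[2L],
              sqrt(sum(x$direction^2))))
  invisible(x)
}

#' Mann-Whitney rank-sum test for two speed samples
#'
#' Computes the U statistic from midranks. The two-sided p-value is exact —
#' by complete enumeration of all group labelings — when
#' `choose(n1 + n2, n1)` is at most `exact_limit`; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' Exactness is decided by enumeration cost rather than by `n1 * n2`, since
#' full enumeration is infeasible already at two groups of 20.
#'
#' @param a,b numeric vectors of speeds (both nonempty).
#' @param exact_limit largest number of labelings enumerated exactly.
#' @return A `rank_sum_result` list: `U` (the reported statistic,
#'   `min(U_a, U_b)`), `U_a`, `U_b`, `p` (two-sided), `n1`, `n2`, `method`.
#'   `U_a + U_b = n1 * n2` always.
#' @export
rank_sum_test <- function(a, b, exact_limit = 2e5) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be nonempty")
  if (any(!is.finite(c(a, b)))) stop("inputs must be finite")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))             # midranks
  Ra <- sum(r[seq_len(n1)])
  Ua <- Ra - n1 * (n1 + 1) / 2
  Ub <- n1 * n2 - Ua
  U <- min(Ua, Ub)
  if (choose(n1 + n2, n1) <= exact_limit) {
    p <- exact_ranksum_p(r, n1, Ua)
    method <- "exact enumeration"
  } else {
    p <- normal_ranksum_p(r, n1, n2, Ua)
    method <- "normal approximation"
  }
  structure(list(U = U, U_a = Ua, U_b = Ub, p = p, n1 = n1, n2 = n2,
                 method = method),
            class = "rank_sum_result")
}

# Exact two-sided p: enumerate every choice of n1 ranks out of the pooled
# midranks and count labelings at least as extreme (|U - n1 n2/2|) as observed.
exact_ranksum_p <- function(r, n1, Ua_obs) {
  n <- length(r); n2 <- n - n1
  mid <- n1 * n2 / 2
  obs_dev <- abs(Ua_obs - mid)
  combos <- utils::combn(n, n1)
  Ras <- colSums(matrix(r[combos], nrow = n1))
  Uas <- Ras - n1 * (n1 + 1) / 2
  # tolerance guards midrank halves against float round-off
  mean(abs(Uas - mid) >= obs_dev - 1e-9)
}

# Normal approximation with tie correction and continuity correction.
normal_ranksum_p <- function(r, n1, n2, Ua) {
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- (abs(Ua - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum: U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}
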