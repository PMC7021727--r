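# Constant-velocity Kalman tracking of refined bead detections.
#
# State is (x, y, vx, vy) in pixels and pixels/frame. The motion error Q is
# deliberately inflated relative to the measurement error R: LoG refinement
# yields strong, well-localized detections, whereas the constant-velocity
# prediction is the weaker assumption for beads that jitter between captures.

#' Constant-velocity Kalman model
#'
#' @param process_noise 4x4 process-noise covariance Q (px^2 and
#'   (px/frame)^2), or a length-4 vector of diagonal entries. Default
#'   `diag(c(0.5, 0.5, 1, 1))`, larger than the measurement noise.
#' @param measurement_noise 2x2 measurement covariance R (px^2) or length-2
#'   diagonal. Default `diag(c(0.25, 0.25))`.
#' @param initial_position_var initial position variance (px^2); defaults to
#'   the measurement variance.
#' @param initial_velocity_var initial velocity variance ((px/frame)^2).
#'   `NULL` resolves to `gate_radius^2` at tracking time, so the first
#'   update after a second sighting effectively learns the velocity from the
#'   displacement.
#' @return A `kalman_model` list with `A` (transition), `H` (observation),
#'   `Q`, `R`, and the initial variances.
#' @export
kalman_model <- function(process_noise = c(0.5, 0.5, 1, 1),
                         measurement_noise = c(0.25, 0.25),
                         initial_position_var = NULL,
                         initial_velocity_var = NULL) {
  Q <- if (is.matrix(process_noise)) process_noise else diag(process_noise, 4)
  R <- if (is.matrix(measurement_noise)) measurement_noise
       else diag(measurement_noise, 2)
  check_psd(Q, "process_noise")
  check_psd(R, "measurement_noise")
  A <- diag(1, 4); A[1, 3] <- 1; A[2, 4] <- 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  if (is.null(initial_position_var)) initial_position_var <- max(diag(R))
  structure(list(A = A, H = H, Q = Q, R = R,
                 initial_position_var = initial_position_var,
                 initial_velocity_var = initial_velocity_var),
            class = "kalman_model")
}

check_psd <- function(M, name) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop(sprintf("'%s' must be symmetric", name))
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(sprintf("'%s' must be positive semidefinite", name))
  }
  invisible(M)
}

symmetrize <- function(M) (M + t(M)) / 2

#' Kalman predict step
#'
#' Advances a state by the constant-velocity transition and propagates the
#' covariance as `A P A' + Q`, re-symmetrizing to keep it PSD.
#'
#' @param state length-4 numeric `(x, y, vx, vy)`.
#' @param P 4x4 covariance.
#' @param model a [kalman_model()].
#' @return List with `state` and `P`.
#' @export
kf_predict <- function(state, P, model) {
  state <- as.numeric(model$A %*% state)
  P <- symmetrize(model$A %*% P %*% t(model$A) + model$Q)
  list(state = state, P = P)
}

#' Kalman update step
#'
#' Standard gain-weighted correction of a predicted state by an observed
#' position, using the Joseph-form covariance update for numerical PSD
#' preservation. As R -> 0 the corrected position approaches the detection;
#' as R -> infinity it approaches the prediction.
#'
#' @param state,P predicted state and covariance from [kf_predict()].
#' @param z observed position `(x, y)` in pixels.
#' @param model a [kalman_model()].
#' @return List with corrected `state` and `P`.
#' @export
kf_update <- function(state, P, z, model) {
  if (any(!is.finite(P))) stop("covariance is not finite")
  ev <- eigen(symmetrize(P), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1)) {
    stop("covariance is not positive semidefinite")
  }
  H <- model$H; R <- model$R
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  innov <- as.numeric(z) - as.numeric(H %*% state)
  state <- as.numeric(state + K %*% innov)
  IKH <- diag(1, 4) - K %*% H
  P <- symmetrize(IKH %*% P %*% t(IKH) + K %*% R %*% t(K))
  list(state = state, P = P)
}

#' Tracking configuration
#'
#' @param gate_radius association gate in pixels: a detection farther than
#'   this from a track's predicted position can never be linked to it.
#' @param max_misses consecutive coasted (unassigned) frames tolerated before
#'   a track is terminated at its last assignment.
#' @param min_visible_frames minimum number of frames with an assigned
#'   detection for a track to be reported; prunes spurious short-lived
#'   tracks that are biologically unlikely.
#' @return A `track_config` list.
#' @export
track_config <- function(gate_radius = 10, max_misses = 3,
                         min_visible_frames = 5) {
  if (gate_radius <= 0) stop("'gate_radius' must be positive")
  if (min_visible_frames < 2) stop("'min_visible_frames' must be >= 2")
  if (max_misses < 0) stop("'max_misses' must be >= 0")
  structure(list(gate_radius = gate_radius, max_misses = max_misses,
                 min_visible_frames = min_visible_frames),
            class = "track_config")
}

# Hungarian algorithm (augmenting path with potentials), O(n^3).
# cost: n x m matrix. Returns an integer vector a of length n with a[i] the
# column assigned to row i (NA if unassigned when n > m).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); tmp <- n; n <- nrow(cost); m <- ncol(cost)
               transposed <- TRUE }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  if (transposed) {
    b <- rep(NA_integer_, tmp)
    for (i in seq_len(n)) if (!is.na(a[i])) b[a[i]] <- i
    a <- b
  }
  a
}

#' Associate predicted tracks with frame detections
#'
#' Globally minimum-cost one-to-one matching between predicted track
#' positions and detection positions under the Euclidean distance, with
#' pairings beyond `gate_radius` forbidden.
#'
#' @param pred numeric matrix (n x 2) of predicted track positions.
#' @param obs numeric matrix (m x 2) of detection positions.
#' @param gate_radius gate in pixels.
#' @return Integer vector of length n: the detection index matched to each
#'   track, or `NA` for a coasting track.
#' @export
associate <- function(pred, obs, gate_radius) {
  n <- nrow(pred); m <- nrow(obs)
  if (n == 0L) return(integer(0))
  if (m == 0L) return(rep(NA_integer_, n))
  d <- sqrt(outer(pred[, 1L], obs[, 1L], `-`)^2 +
            outer(pred[, 2L], obs[, 2L], `-`)^2)
  big <- gate_radius * (n + m + 1) * 1e3 + 1e3
  cost <- ifelse(d <= gate_radius, d, big)
  a <- solve_assignment(cost)
  for (i in seq_len(n)) {
    if (!is.na(a[i]) && d[i, a[i]] > gate_radius) a[i] <- NA_integer_
  }
  a
}

#' Track detections through time
#'
#' Links detections frame by frame with the constant-velocity Kalman filter:
#' active tracks are predicted forward, detections are assigned by
#' minimum-cost gated matching, matched tracks are corrected, unmatched
#' tracks coast, and tracks exceeding `max_misses` consecutive coasts are
#' terminated at their last assignment. Unmatched detections spawn new
#' tracks (zero initial velocity, large initial velocity variance). Only
#' tracks with at least `min_visible_frames` assigned detections are
#' reported. The result is deterministic given its inputs.
#'
#' @param det detections data frame covering frames `0 .. T-1` (frames with
#'   no detections are allowed).
#' @param model a [kalman_model()].
#' @param config a [track_config()].
#' @param n_frames total frame count; inferred from the detections when
#'   missing.
#' @return Object of class `bead_tracks`: a list of tracks, each a list with
#'   `id`, `samples` (data frame `frame, x, y, det_x, det_y, assigned`),
#'   `state_history`, and `status`. Filtered positions are in `x, y`; raw
#'   detection coordinates in `det_x, det_y` (NA on coasted frames).
#' @export
track_sequence <- function(det, model = kalman_model(),
                           config = track_config(), n_frames = NULL) {
  stopifnot(inherits(model, "kalman_model"), inherits(config, "track_config"))
  if (nrow(det) == 0L) return(structure(list(), class = "bead_tracks"))
  if (is.null(n_frames)) n_frames <- max(det$frame) + 1L
  vel_var <- model$initial_velocity_var
  if (is.null(vel_var)) vel_var <- config$gate_radius^2
  P0 <- diag(c(model$initial_position_var, model$initial_position_var,
               vel_var, vel_var))
  active <- list()
  done <- list()
  next_id <- 1L
  finalize <- function(tr) {
    # truncate trailing coasts so termination is at the last assignment
    last <- max(which(tr$samples$assigned == 1L))
    tr$samples <- tr$samples[seq_len(last), , drop = FALSE]
    tr$state_history <- tr$state_history[seq_len(last)]
    tr$status <- "terminated"
    tr
  }
  for (t in 0:(n_frames - 1L)) {
    d <- det[det$frame == t, , drop = FALSE]
    # predict
    for (k in seq_along(active)) {
      pr <- kf_predict(active[[k]]$state, active[[k]]$P, model)
      active[[k]]$state <- pr$state
      active[[k]]$P <- pr$P
    }
    if (length(active) > 0L) {
      pred <- do.call(rbind, lapply(active, function(tr) tr$state[1:2]))
      obs <- cbind(d$x, d$y)
      asg <- associate(pred, obs, config$gate_radius)
    } else {
      asg <- integer(0)
    }
    used_det <- rep(FALSE, nrow(d))
    keep <- rep(TRUE, length(active))
    for (k in seq_along(active)) {
      tr <- active[[k]]
      if (!is.na(asg[k])) {
        j <- asg[k]
        used_det[j] <- TRUE
        up <- kf_update(tr$state, tr$P, c(d$x[j], d$y[j]), model)
        tr$state <- up$state; tr$P <- up$P; tr$misses <- 0L
        tr$n_assigned <- tr$n_assigned + 1L
        tr$samples <- rbind(tr$samples, data.frame(
          frame = t, x = tr$state[1L], y = tr$state[2L],
          det_x = d$x[j], det_y = d$y[j], assigned = 1L))
      } else {
        tr$misses <- tr$misses + 1L
        tr$samples <- rbind(tr$samples, data.frame(
          frame = t, x = tr$state[1L], y = tr$state[2L],
          det_x = NA_real_, det_y = NA_real_, assigned = 0L))
      }
      tr$state_history <- c(tr$state_history,
                            list(list(state = tr$state, P = tr$P)))
      if (tr$misses > config$max_misses) {
        done[[length(done) + 1L]] <- finalize(tr)
        keep[k] <- FALSE
      } else {
        active[[k]] <- tr
      }
    }
    active <- active[keep]
    # spawn new tracks from unmatched detections
    for (j in which(!used_det)) {
      st <- c(d$x[j], d$y[j], 0, 0)
      active[[length(active) + 1L]] <- list(
        id = next_id, state = st, P = P0, misses = 0L, n_assigned = 1L,
        samples = data.frame(frame = t, x = d$x[j], y = d$y[j],
                             det_x = d$x[j], det_y = d$y[j], assigned = 1L),
        state_history = list(list(state = st, P = P0)))
      next_id <- next_id + 1L
    }
  }
  for (tr in active) done[[length(done) + 1L]] <- finalize(tr)
  done <- Filter(function(tr) tr$n_assigned >= config$min_visible_frames, done)
  done <- done[order(vapply(done, function(tr) tr$id, integer(1)))]
  done <- lapply(done, function(tr) {
    rownames(tr$samples) <- NULL
    tr[c("id", "samples", "state_history", "n_assigned", "status")]
  })
  structure(done, class = "bead_tracks")
}

#' @export
print.bead_tracks <- function(x, ...) {
  cat(sprintf("bead_tracks: %d reported tracks\n", length(x)))
  invisible(x)
}

#' Flatten tracks to a data frame
#'
#' @param x a `bead_tracks` object.
#' @param row.names,optional,... ignored; present for the generic.
#' @return Data frame with columns
#'   `track_id, frame, x, y, det_x, det_y, assigned`.
#' @export
as.data.frame.bead_tracks <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  if (length(x) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), det_x = numeric(),
                      det_y = numeric(), assigned = integer()))
  }
  do.call(rbind, lapply(x, function(tr) {
    cbind(track_id = tr$id, tr$samples)
  }))
}
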