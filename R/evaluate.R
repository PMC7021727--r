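# Ground-truth evaluation of detections and tracks on synthetic scenes.
# These quantify how well the pipeline recovers what the generator put in:
# detection precision/recall/localization, and per-bead track recovery.

#' Detection precision, recall and localization error against ground truth
#'
#' Matches detections to true bead positions frame by frame (greedy
#' nearest-first within `match_radius`). Only rows of `truth` passed in are
#' expected; filter beforehand to visible beads inside the detector's valid
#' border region.
#'
#' @param det detections data frame.
#' @param truth ground-truth data frame with `frame`, `x`, `y` (0-based),
#'   e.g. from [generate_bead_video()] filtered to `visible` beads.
#' @param match_radius maximum detection-to-truth distance (px) counted as a
#'   hit.
#' @return List: `precision`, `recall`, `mean_localization_error` (px, over
#'   matched pairs), `n_true`, `n_detections`, `n_matched`.
#' @export
detection_metrics <- function(det, truth, match_radius = 2) {
  n_matched <- 0L
  errs <- numeric(0)
  for (f in unique(c(det$frame, truth$frame))) {
    d <- det[det$frame == f, , drop = FALSE]
    tt <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(d) == 0L || nrow(tt) == 0L) next
    dist <- sqrt(outer(d$x, tt$x, `-`)^2 + outer(d$y, tt$y, `-`)^2)
    while (TRUE) {
      k <- which.min(dist)
      if (length(k) == 0L || dist[k] > match_radius) break
      i <- (k - 1L) %% nrow(dist) + 1L
      j <- (k - 1L) %/% nrow(dist) + 1L
      n_matched <- n_matched + 1L
      errs <- c(errs, dist[k])
      dist[i, ] <- Inf
      dist[, j] <- Inf
      if (all(!is.finite(dist))) break
    }
  }
  list(precision = if (nrow(det) > 0L) n_matched / nrow(det) else NA_real_,
       recall = if (nrow(truth) > 0L) n_matched / nrow(truth) else NA_real_,
       mean_localization_error = if (length(errs)) mean(errs) else NA_real_,
       n_true = nrow(truth), n_detections = nrow(det),
       n_matched = n_matched)
}

#' Per-bead track recovery against ground truth
#'
#' Each reported track is attributed to the ground-truth bead closest to the
#' majority of its assigned detections (within `dist_tol`). A bead counts as
#' *recovered as a single track* when exactly one track is attributed to it
#' and that track's matched samples cover at least `min_coverage` of the
#' bead's ground-truth frames. Pass `truth` already restricted to the frames
#' where the bead was genuinely observable (visible and inside the
#' detector's valid region).
#'
#' @param tracks a `bead_tracks` object.
#' @param truth ground-truth data frame with `bead_id`, `frame`, `x`, `y`.
#' @param dist_tol sample-to-truth match distance (px).
#' @param min_coverage minimum fraction of the bead's frames covered.
#' @return List with `per_bead` (data frame: `bead_id`, `n_frames_true`,
#'   `n_tracks`, `coverage`, `recovered_single`), `recovered_fraction`, and
#'   `track_bead` (the bead attributed to each track, NA for unmatched).
#' @export
track_recovery <- function(tracks, truth, dist_tol = 3, min_coverage = 0.5) {
  beads <- sort(unique(truth$bead_id))
  track_bead <- rep(NA_integer_, length(tracks))
  matched_frames <- vector("list", length(beads))
  names(matched_frames) <- as.character(beads)
  for (k in seq_along(tracks)) {
    s <- tracks[[k]]$samples
    s <- s[s$assigned == 1L, , drop = FALSE]
    hits <- integer(0)
    hit_frames <- list()
    for (i in seq_len(nrow(s))) {
      tt <- truth[truth$frame == s$frame[i], , drop = FALSE]
      if (nrow(tt) == 0L) next
      dd <- sqrt((tt$x - s$x[i])^2 + (tt$y - s$y[i])^2)
      j <- which.min(dd)
      if (dd[j] <= dist_tol) {
        hits <- c(hits, tt$bead_id[j])
        hit_frames <- c(hit_frames, list(c(tt$bead_id[j], s$frame[i])))
      }
    }
    if (length(hits) == 0L) next
    maj <- as.integer(names(which.max(table(hits))))
    # attribution requires the bead to account for most of the track's
    # assigned samples, so a track that merely crosses a bead is not counted
    if (sum(hits == maj) <= 0.5 * nrow(s)) next
    track_bead[k] <- maj
    fr <- vapply(hit_frames[vapply(hit_frames, `[`, numeric(1), 1L) == maj],
                 `[`, numeric(1), 2L)
    key <- as.character(maj)
    matched_frames[[key]] <- union(matched_frames[[key]], fr)
  }
  per_bead <- do.call(rbind, lapply(beads, function(b) {
    nf <- length(unique(truth$frame[truth$bead_id == b]))
    nt <- sum(track_bead == b, na.rm = TRUE)
    cov <- length(matched_frames[[as.character(b)]]) / max(nf, 1L)
    data.frame(bead_id = b, n_frames_true = nf, n_tracks = nt,
               coverage = cov,
               recovered_single = (nt == 1L && cov >= min_coverage))
  }))
  list(per_bead = per_bead,
       recovered_fraction = mean(per_bead$recovered_single),
       track_bead = track_bead)
}
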