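# Detections travel as a data.frame with columns
#   frame    0-based time index
#   x, y     0-based position in pixels (x = column, y = row)
#   scale    radius of the winning filter (px)
#   response signed LoG response at the optimum (negative for bright beads)
# and a "stage" attribute recording the refinement provenance.

new_detections <- function(frame = integer(), x = numeric(), y = numeric(),
                           scale = numeric(), response = numeric(),
                           stage = "raw") {
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y), scale = as.numeric(scale),
                   response = as.numeric(response))
  df <- df[order(df$frame, df$y, df$x, df$scale), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "stage") <- stage
  df
}

set_stage <- function(det, stage) {
  attr(det, "stage") <- stage
  det
}

#' Detection provenance stage
#'
#' @param det a detections data frame as produced by [extract_local_optima()]
#'   and the refinement steps.
#' @return The refinement stage label: one of `"raw"`, `"suppressed"`,
#'   `"merged"`, `"de-stationaried"`.
#' @export
detection_stage <- function(det) attr(det, "stage")

# Reflect (symmetric, edge included) padding by w pixels on every side.
pad_reflect <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  ri <- c(w:1, 1:h, h:(h - w + 1L))
  ci <- c(w:1, 1:wd, wd:(wd - w + 1L))
  m[ri, ci]
}

#' Apply the LoG filter bank to one frame
#'
#' Correlates the frame with each kernel of the bank. The image is
#' reflect-padded so each response map has the same size as the input; the
#' kernels are symmetric under negation, so correlation and convolution
#' coincide. Bright beads on a dark background produce negative responses.
#'
#' @param frame numeric `H x W` matrix of finite, nonnegative intensities.
#' @param bank a [build_log_bank()] object.
#' @return Named list of `H x W` response maps, one per radius.
#' @export
apply_log <- function(frame, bank) {
  stopifnot(is.matrix(frame), inherits(bank, "log_bank"))
  if (!all(is.finite(frame))) stop("frame must contain finite values")
  sides <- vapply(bank$kernels, nrow, integer(1))
  if (min(dim(frame)) < max(sides)) {
    stop(sprintf("image (%d x %d) is smaller than the largest kernel (%d px)",
                 nrow(frame), ncol(frame), max(sides)))
  }
  maps <- lapply(bank$kernels, function(k) {
    w <- (nrow(k) - 1L) %/% 2L
    padded <- pad_reflect(frame, w)
    r <- EBImage::filter2(padded, k, boundary = "circular")
    r[(w + 1L):(w + nrow(frame)), (w + 1L):(w + ncol(frame)), drop = FALSE]
  })
  names(maps) <- as.character(bank$radii)
  maps
}

# Interior local extrema of a matrix under the 8-neighborhood, with plateau
# resolution: a flat extremal region contributes its lexicographically
# smallest pixel (row, then column). Returns (row, col) pairs, 1-based.
# For kind = "min" a pixel must be <= all neighbors and its plateau strictly
# below every surrounding value; "max" is the mirror.
local_extrema <- function(m, kind = c("min", "max")) {
  kind <- match.arg(kind)
  if (kind == "max") m <- -m
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) return(matrix(integer(0), 0L, 2L))
  ri <- 2L:(h - 1L); ci <- 2L:(w - 1L)
  ctr <- m[ri, ci, drop = FALSE]
  nmin <- array(Inf, dim(ctr))
  neq <- array(FALSE, dim(ctr))   # any neighbor exactly equal
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- m[ri + dr, ci + dc, drop = FALSE]
    nmin <- pmin(nmin, nb)
    neq <- neq | (nb == ctr)
  }
  strict <- which(ctr < nmin, arr.ind = TRUE)
  out <- cbind(strict[, 1L] + 1L, strict[, 2L] + 1L)
  flat <- which(ctr <= nmin & neq, arr.ind = TRUE)
  if (nrow(flat) > 0L) {
    out <- rbind(out, resolve_plateaus(m, cbind(flat[, 1L] + 1L,
                                                flat[, 2L] + 1L)))
  }
  out
}

# Group plateau candidates (equal value, <= all neighbors) into 8-connected
# equal-value components; a component survives only if every surrounding
# pixel is strictly greater, and is represented by its lexicographically
# smallest member.
resolve_plateaus <- function(m, cand) {
  if (nrow(cand) == 0L) return(cand)
  key <- (cand[, 1L] - 1L) * ncol(m) + cand[, 2L]
  in_cand <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cand))) assign(as.character(key[i]), i, envir = in_cand)
  seen <- logical(nrow(cand))
  keep <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    if (seen[i]) next
    # flood fill the equal-value component
    comp <- i; queue <- i; seen[i] <- TRUE
    val <- m[cand[i, 1L], cand[i, 2L]]
    ok <- TRUE
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      r0 <- cand[j, 1L]; c0 <- cand[j, 2L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r <- r0 + dr; c <- c0 + dc
        if (m[r, c] == val) {
          k <- as.character((r - 1L) * ncol(m) + c)
          idx <- mget(k, envir = in_cand, ifnotfound = list(NULL))[[1L]]
          if (is.null(idx)) {
            ok <- FALSE  # equal neighbor that is not itself a candidate
          } else if (!seen[idx]) {
            seen[idx] <- TRUE
            comp <- c(comp, idx); queue <- c(queue, idx)
          }
        } else if (m[r, c] < val) {
          ok <- FALSE
        }
      }
    }
    if (ok) {
      cc <- cand[comp, , drop = FALSE]
      best <- order(cc[, 1L], cc[, 2L])[1L]
      keep <- rbind(keep, cc[best, , drop = FALSE])
    }
  }
  keep
}

#' Extract raw detections from LoG response maps
#'
#' Strict local minima in the 8-neighborhood of each scale's response map are
#' kept when their response passes the sensitivity threshold
#' (`response <= -tau`). With an automatic bank (`sensitivity = NULL`), `tau`
#' is `sensitivity_k` times the median absolute deviation of that map.
#' Detections within `ceiling(2 * max(sigma))` pixels of the border are
#' excluded by default to avoid padding artifacts.
#'
#' @param maps response maps from [apply_log()].
#' @param bank the [build_log_bank()] used to produce them.
#' @param frame 0-based frame index stamped on the detections.
#' @param exclude_border drop detections within the largest kernel half-width
#'   of the image border (default `TRUE`).
#' @return A detections data frame (stage `"raw"`). Empty is valid.
#' @export
extract_local_optima <- function(maps, bank, frame = 0L,
                                 exclude_border = TRUE) {
  stopifnot(length(maps) == length(bank$radii))
  h <- nrow(maps[[1L]]); w <- ncol(maps[[1L]])
  margin <- if (exclude_border) ceiling(2 * max(bank$sigmas)) else 0L
  out <- vector("list", length(maps))
  for (s in seq_along(maps)) {
    m <- maps[[s]]
    tau <- if (is.null(bank$sensitivity)) {
      # robust automatic cut: k MADs below the map median. The truncated
      # kernel is not zero-sum, so a constant background DC-shifts the whole
      # map; anchoring at the median keeps the cut noise-relative. For a
      # zero-background image this is exactly k * MAD.
      v <- as.vector(m)
      max(0, bank$sensitivity_k * stats::mad(v) - stats::median(v))
    } else bank$sensitivity
    pts <- local_extrema(m, "min")
    if (nrow(pts) == 0L) next
    resp <- m[pts]
    keep <- resp <= -tau
    if (margin > 0L) {
      keep <- keep &
        pts[, 1L] > margin & pts[, 1L] <= h - margin &
        pts[, 2L] > margin & pts[, 2L] <= w - margin
    }
    if (!any(keep)) next
    pts <- pts[keep, , drop = FALSE]
    out[[s]] <- data.frame(frame = frame, x = pts[, 2L] - 1, y = pts[, 1L] - 1,
                           scale = bank$radii[s], response = m[pts])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(new_detections())
  df <- do.call(rbind, out)
  new_detections(df$frame, df$x, df$y, df$scale, df$response, stage = "raw")
}

#' Non-minima suppression of overlapping detections
#'
#' Among any pair of same-frame detections closer than `radius` (Euclidean),
#' only the stronger one (more negative response) survives; ties are broken
#' by `(frame, y, x, scale)` lexicographic order. Operates across scales, so
#' one bead detected at several radii keeps only its strongest-response
#' scale. The filter is a pure dominance rule and therefore idempotent.
#'
#' @param det detections data frame.
#' @param radius suppression radius in pixels (pairs at exactly `radius`
#'   do not interact).
#' @return The surviving detections, stage `"suppressed"`.
#' @export
nonminima_suppression <- function(det, radius) {
  stopifnot(is.data.frame(det), radius > 0)
  if (nrow(det) <= 1L) return(set_stage(det, "suppressed"))
  keep <- logical(nrow(det))
  for (f in unique(det$frame)) {
    idx <- which(det$frame == f)
    d <- det[idx, , drop = FALSE]
    n <- length(idx)
    dx <- outer(d$x, d$x, `-`); dy <- outer(d$y, d$y, `-`)
    close <- (dx * dx + dy * dy) < radius^2
    diag(close) <- FALSE
    # rank: strongest (most negative response) first, ties lexicographic
    rk <- order(d$response, d$frame, d$y, d$x, d$scale)
    pos <- integer(n); pos[rk] <- seq_len(n)
    dominated <- vapply(seq_len(n), function(i) {
      any(close[i, ] & pos < pos[i])
    }, logical(1))
    keep[idx] <- !dominated
  }
  set_stage(det[keep, , drop = FALSE], "suppressed")
}

#' Refinement configuration
#'
#' Parameters of the two-step detection refinement: (1) a Gaussian heatmap
#' built from the detection locations merges nearby beads into single
#' detections; (2) complete-linkage clustering under the Chebyshev metric
#' removes beads that sit still for too many frames.
#'
#' @param heatmap_sigma width (px) of the per-detection Gaussian in the merge
#'   heatmap; defaults to 4, the mean of the default bank radii.
#' @param heatmap_threshold absolute cut on heatmap local maxima. `NULL`
#'   (default) resolves to half of a single isolated detection's peak,
#'   `0.5 / (2 * pi * heatmap_sigma^2)`, so isolated beads always survive.
#' @param cheb_link_dist dendrogram cut (px) for the complete-linkage
#'   Chebyshev clustering; default 2.
#' @param max_stationary_frames a cluster spanning more than this many
#'   distinct frames is deleted wholesale. `NULL` (default) resolves to half
#'   the sequence length at use time. Must resolve to >= 2.
#' @return A `refine_config` list.
#' @export
refine_config <- function(heatmap_sigma = 4, heatmap_threshold = NULL,
                          cheb_link_dist = 2, max_stationary_frames = NULL) {
  if (heatmap_sigma <= 0) stop("'heatmap_sigma' must be positive")
  if (cheb_link_dist <= 0) stop("'cheb_link_dist' must be positive")
  if (is.null(heatmap_threshold)) {
    heatmap_threshold <- 0.5 / (2 * pi * heatmap_sigma^2)
  }
  if (heatmap_threshold <= 0) stop("'heatmap_threshold' must be positive")
  if (!is.null(max_stationary_frames) && max_stationary_frames < 2) {
    stop("'max_stationary_frames' must be >= 2")
  }
  structure(list(heatmap_sigma = heatmap_sigma,
                 heatmap_threshold = heatmap_threshold,
                 cheb_link_dist = cheb_link_dist,
                 max_stationary_frames = max_stationary_frames),
            class = "refine_config")
}

#' Merge nearby detections through a Gaussian heatmap
#'
#' For each frame, unit-mass Gaussians of width `heatmap_sigma` are summed at
#' the detection locations over the pixel grid. Heatmap local maxima at or
#' above `heatmap_threshold` become merged detections: the position is the
#' maximum's location, and the response and scale are those of the strongest
#' attributed member. Detections farther than `3 * heatmap_sigma` from every
#' surviving maximum are dropped.
#'
#' @param det detections data frame (typically stage `"suppressed"`).
#' @param config a [refine_config()].
#' @param dim image dimensions `c(H, W)` in pixels.
#' @return Merged detections, stage `"merged"`.
#' @export
merge_by_heatmap <- function(det, config, dim) {
  stopifnot(inherits(config, "refine_config"), length(dim) == 2L)
  if (nrow(det) == 0L) return(set_stage(det, "merged"))
  sg <- config$heatmap_sigma
  win <- ceiling(4 * sg)
  out <- list()
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, , drop = FALSE]
    hm <- matrix(0, dim[1L], dim[2L])
    for (i in seq_len(nrow(d))) {
      r0 <- d$y[i] + 1; c0 <- d$x[i] + 1
      rr <- max(1L, floor(r0 - win)):min(dim[1L], ceiling(r0 + win))
      cc <- max(1L, floor(c0 - win)):min(dim[2L], ceiling(c0 + win))
      gy <- exp(-(rr - r0)^2 / (2 * sg^2))
      gx <- exp(-(cc - c0)^2 / (2 * sg^2))
      hm[rr, cc] <- hm[rr, cc] + outer(gy, gx) / (2 * pi * sg^2)
    }
    pk <- local_extrema(hm, "max")
    if (nrow(pk) > 0L) pk <- pk[hm[pk] >= config$heatmap_threshold, ,
                                drop = FALSE]
    if (nrow(pk) == 0L) next
    # attribute each detection to its nearest surviving maximum
    dmat <- outer(d$y, pk[, 1L] - 1, `-`)^2 + outer(d$x, pk[, 2L] - 1, `-`)^2
    nearest <- max.col(-dmat, ties.method = "first")
    within <- dmat[cbind(seq_len(nrow(d)), nearest)] <= (3 * sg)^2
    for (p in seq_len(nrow(pk))) {
      members <- which(within & nearest == p)
      if (length(members) == 0L) next
      best <- members[order(d$response[members], d$y[members], d$x[members],
                            d$scale[members])[1L]]
      out[[length(out) + 1L]] <- data.frame(
        frame = f, x = pk[p, 2L] - 1, y = pk[p, 1L] - 1,
        scale = d$scale[best], response = d$response[best])
    }
  }
  if (length(out) == 0L) return(set_stage(new_detections(), "merged"))
  df <- do.call(rbind, out)
  new_detections(df$frame, df$x, df$y, df$scale, df$response, stage = "merged")
}

#' Remove detections that are stationary for too many frames
#'
#' All detections, pooled over time, are clustered agglomeratively with
#' complete linkage under the Chebyshev (L-infinity) distance; the dendrogram
#' is cut at `cheb_link_dist`. Any cluster whose members span more than
#' `max_stationary_frames` distinct frames marks a bead that never moved and
#' is deleted wholesale (stuck beads and debris). Survivors are unchanged.
#'
#' @param det detections data frame across all frames.
#' @param config a [refine_config()]. A `NULL` `max_stationary_frames`
#'   resolves to `ceiling(n_frames / 2)`.
#' @param n_frames sequence length, used for that default; inferred from the
#'   detections when missing.
#' @return Detections with stationary clusters removed,
#'   stage `"de-stationaried"`.
#' @export
remove_stationary <- function(det, config, n_frames = NULL) {
  stopifnot(inherits(config, "refine_config"))
  if (nrow(det) < 2L) return(set_stage(det, "de-stationaried"))
  n_stat <- config$max_stationary_frames
  if (is.null(n_stat)) {
    if (is.null(n_frames)) n_frames <- max(det$frame) + 1L
    n_stat <- max(2L, ceiling(n_frames / 2))
  }
  hc <- stats::hclust(stats::dist(cbind(det$x, det$y), method = "maximum"),
                      method = "complete")
  cl <- stats::cutree(hc, h = config$cheb_link_dist)
  span <- tapply(det$frame, cl, function(fr) length(unique(fr)))
  drop_cl <- as.integer(names(span)[span > n_stat])
  set_stage(det[!(cl %in% drop_cl), , drop = FALSE], "de-stationaried")
}

#' Detect beads across a whole image sequence
#'
#' Runs the full per-frame detection chain (LoG filtering, local-minima
#' extraction with sensitivity threshold, non-minima suppression, heatmap
#' merging) and then the cross-frame stationary-bead removal.
#'
#' @param seq an [image_sequence()].
#' @param bank a [build_log_bank()]; default bank uses radii 3, 4, 5 px.
#' @param refine a [refine_config()].
#' @param suppression_radius non-minima suppression radius in pixels;
#'   defaults to the largest bank radius.
#' @param exclude_border see [extract_local_optima()].
#' @param drop_stationary run [remove_stationary()] at the end
#'   (default `TRUE`).
#' @return Detections data frame over all frames.
#' @export
detect_sequence <- function(seq, bank = build_log_bank(),
                            refine = refine_config(),
                            suppression_radius = NULL,
                            exclude_border = TRUE,
                            drop_stationary = TRUE) {
  stopifnot(inherits(seq, "image_sequence"))
  if (is.null(suppression_radius)) suppression_radius <- max(bank$radii)
  dims <- frame_dim(seq)
  per_frame <- vector("list", n_frames(seq))
  for (t in seq_len(n_frames(seq))) {
    maps <- apply_log(seq$frames[[t]], bank)
    raw <- extract_local_optima(maps, bank, frame = t - 1L,
                                exclude_border = exclude_border)
    sup <- nonminima_suppression(raw, suppression_radius)
    per_frame[[t]] <- merge_by_heatmap(sup, refine, dims)
  }
  det <- do.call(rbind, per_frame)
  det <- new_detections(det$frame, det$x, det$y, det$scale, det$response,
                        stage = "merged")
  if (drop_stationary) {
    det <- remove_stationary(det, refine, n_frames = n_frames(seq))
  }
  det
}
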