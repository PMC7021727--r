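# Synthetic bead videos and linescan traces with known ground truth. The
# generator emulates the ex vivo assay: 1-um latex beads carried over the
# ventricular wall by cilia-driven flow, imaged by widefield fluorescence at
# 20 frames/s, plus stationary decoys (stuck beads, debris) and camera noise.

# Evaluate thunk with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Defines a bead video: flowing beads rendered as isotropic Gaussian spots
#' (`sigma_spot = bead_radius / sqrt(2)`, the same radius-to-width convention
#' the LoG detector uses), advected by a constant flow with per-frame
#' Brownian jitter, plus stationary decoy beads and additive noise.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame; default 0.05 (20 frames/s).
#' @param pixel_size micrometres per pixel; default 0.5.
#' @param n_beads number of flowing beads.
#' @param bead_radius bead radius in pixels; default 3.
#' @param flow_velocity `(vx, vy)` in pixels/frame.
#' @param diffusion_sigma per-frame Brownian jitter (px); 0 for pure
#'   advection.
#' @param n_stationary number of fixed decoy beads.
#' @param detect_prob probability a bead is rendered in a given frame
#'   (models blinking/occlusion; 0.95 means 5% of sightings are missed).
#' @param background,peak background level and bead peak amplitude.
#' @param noise_sigma additive Gaussian noise sd; `peak / noise_sigma` is the
#'   scene SNR.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (intensities
#'   scaled by `poisson_gain` photons per unit, Poisson sampled, rescaled).
#' @param poisson_gain photons per intensity unit for the Poisson model.
#' @param min_separation minimum initial center-to-center distance (px);
#'   `NULL` resolves to `4 * bead_radius`.
#' @param seed integer RNG seed; the whole scene is bit-reproducible.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height = 128, width = 128, n_frames = 100,
                         frame_interval = 0.05, pixel_size = 0.5,
                         n_beads = 15, bead_radius = 3,
                         flow_velocity = c(3, 0), diffusion_sigma = 0.3,
                         n_stationary = 3, detect_prob = 0.95,
                         background = 10, peak = 100, noise_sigma = 10,
                         noise_model = c("gaussian", "poisson"),
                         poisson_gain = 1, min_separation = NULL,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (peak <= noise_sigma || noise_sigma < 0) {
    stop("'peak' must exceed 'noise_sigma' and 'noise_sigma' must be >= 0")
  }
  if (detect_prob <= 0 || detect_prob > 1) {
    stop("'detect_prob' must be in (0, 1]")
  }
  if (n_beads < 0 || n_stationary < 0 || n_frames < 1) {
    stop("counts must be nonnegative and n_frames >= 1")
  }
  if (is.null(min_separation)) min_separation <- 4 * bead_radius
  structure(list(height = height, width = width, n_frames = n_frames,
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 n_beads = n_beads, bead_radius = bead_radius,
                 flow_velocity = flow_velocity,
                 diffusion_sigma = diffusion_sigma,
                 n_stationary = n_stationary, detect_prob = detect_prob,
                 background = background, peak = peak,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 poisson_gain = poisson_gain,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "scene_config")
}

# Rejection-sample initial positions with the margin and separation
# constraints; errors out when the geometry cannot accommodate them.
place_beads <- function(n, height, width, margin, min_sep, max_tries = 5000L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  if (width - 2 * margin <= 0 || height - 2 * margin <= 0) {
    stop("frame too small for the bead margin constraint")
  }
  pos <- matrix(NA_real_, n, 2L)
  placed <- 0L
  for (tries in seq_len(max_tries)) {
    cand <- c(stats::runif(1, margin, width - 1 - margin),
              stats::runif(1, margin, height - 1 - margin))
    if (placed == 0L ||
        min(sqrt((pos[seq_len(placed), 1L] - cand[1L])^2 +
                 (pos[seq_len(placed), 2L] - cand[2L])^2)) >= min_sep) {
      placed <- placed + 1L
      pos[placed, ] <- cand
      if (placed == n) return(pos)
    }
  }
  stop("could not place beads: too many beads for the margin/separation ",
       "constraints")
}

# Add a Gaussian spot of width sigma and amplitude peak at 0-based (x, y).
render_spot <- function(frame, x, y, sigma, peak) {
  h <- nrow(frame); w <- ncol(frame)
  win <- ceiling(4 * sigma)
  rr <- max(1L, floor(y + 1 - win)):min(h, ceiling(y + 1 + win))
  cc <- max(1L, floor(x + 1 - win)):min(w, ceiling(x + 1 + win))
  if (length(rr) == 0L || length(cc) == 0L) return(frame)
  gy <- exp(-((rr - 1) - y)^2 / (2 * sigma^2))
  gx <- exp(-((cc - 1) - x)^2 / (2 * sigma^2))
  frame[rr, cc] <- frame[rr, cc] + peak * outer(gy, gx)
  frame
}

#' Generate a synthetic bead video with ground truth
#'
#' Flowing beads start inside the frame with a margin of at least
#' `4 * bead_radius` and evolve as
#' `x[t+1] = x[t] + flow_velocity + N(0, diffusion_sigma^2)`; beads whose
#' center leaves the frame are dropped from visibility for good. Stationary
#' decoys stay at their initial position. Each bead is rendered in a frame
#' with probability `detect_prob`. All randomness derives from
#' `config$seed`: two calls with the same config are bit-identical.
#'
#' @param config a [scene_config()].
#' @return List with `sequence` (an [image_sequence()]) and `truth`, a data
#'   frame `bead_id, frame, x, y, visible, stationary` (0-based frames and
#'   pixel coordinates).
#' @export
generate_bead_video <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    margin <- 4 * config$bead_radius
    n_all <- config$n_beads + config$n_stationary
    pos0 <- place_beads(n_all, config$height, config$width, margin,
                        config$min_separation)
    stationary <- c(rep(FALSE, config$n_beads),
                    rep(TRUE, config$n_stationary))
    sigma_spot <- config$bead_radius / sqrt(2)
    frames <- vector("list", config$n_frames)
    truth <- vector("list", config$n_frames)
    pos <- pos0
    gone <- rep(FALSE, n_all)
    for (t in seq_len(config$n_frames)) {
      if (t > 1L) {
        mv <- which(!stationary)
        if (length(mv) > 0L) {
          pos[mv, 1L] <- pos[mv, 1L] + config$flow_velocity[1L] +
            stats::rnorm(length(mv), 0, config$diffusion_sigma)
          pos[mv, 2L] <- pos[mv, 2L] + config$flow_velocity[2L] +
            stats::rnorm(length(mv), 0, config$diffusion_sigma)
        }
      }
      gone <- gone | pos[, 1L] < 0 | pos[, 1L] > config$width - 1 |
        pos[, 2L] < 0 | pos[, 2L] > config$height - 1
      seen <- stats::runif(n_all) <= config$detect_prob & !gone
      fr <- matrix(config$background, config$height, config$width)
      for (b in which(seen)) {
        fr <- render_spot(fr, pos[b, 1L], pos[b, 2L], sigma_spot,
                          config$peak)
      }
      if (config$noise_model == "gaussian") {
        if (config$noise_sigma > 0) {
          fr <- fr + matrix(stats::rnorm(length(fr), 0, config$noise_sigma),
                            nrow(fr))
        }
      } else {
        fr <- stats::rpois(length(fr), pmax(fr, 0) * config$poisson_gain) /
          config$poisson_gain
        fr <- matrix(fr, config$height, config$width)
      }
      fr[fr < 0] <- 0
      frames[[t]] <- fr
      truth[[t]] <- data.frame(bead_id = seq_len(n_all), frame = t - 1L,
                               x = pos[, 1L], y = pos[, 2L],
                               visible = seen, stationary = stationary)
    }
    list(sequence = image_sequence(frames,
                                   frame_interval = config$frame_interval,
                                   pixel_size = config$pixel_size),
         truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic linescan trace
#'
#' A sinusoid of the requested frequency plus seeded Gaussian noise at the
#' requested amplitude signal-to-noise ratio, mirroring the confocal
#' linescan geometry (529 Hz, 5000 cycles by default).
#'
#' @param frequency oscillation frequency in Hz, strictly below Nyquist.
#' @param sampling_rate sampling rate in Hz.
#' @param n number of samples.
#' @param snr amplitude SNR (sinusoid amplitude over noise sd); `Inf` gives
#'   a noise-free sinusoid.
#' @param offset,amplitude baseline intensity and oscillation amplitude.
#' @param seed integer RNG seed.
#' @return A [linescan_trace()].
#' @export
generate_linescan <- function(frequency, sampling_rate = 529, n = 5000,
                              snr = Inf, offset = 100, amplitude = 10,
                              seed = 1L) {
  if (frequency <= 0 || frequency >= sampling_rate / 2) {
    stop("'frequency' must lie strictly between 0 and Nyquist")
  }
  if (snr <= 0) stop("'snr' must be positive")
  tt <- (seq_len(n) - 1L) / sampling_rate
  x <- offset + amplitude * sin(2 * pi * frequency * tt)
  if (is.finite(snr)) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, amplitude / snr))
  }
  linescan_trace(x, sampling_rate = sampling_rate)
}
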