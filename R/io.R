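# File I/O and the end-to-end pipeline: TIFF/PNG sequence reading, CSV and
# JSON artifacts, YAML run configuration with strict key checking, and a
# deterministic all-in-one runner.

#' Read an image sequence from disk
#'
#' Accepts a multi-page grayscale TIFF or a directory of lexicographically
#' ordered PNG/TIFF frames. Bit depth is normalized to floating intensities
#' in `[0, 1]`. RGB frames are averaged to grayscale.
#'
#' @param path file or directory path.
#' @param frame_interval,pixel_size acquisition metadata to attach.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, frame_interval = 0.05, pixel_size = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no frames: directory holds no TIFF/PNG")
    frames <- lapply(files, read_one_frame)
  } else if (file.exists(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) {
                        stop("could not read TIFF '", path, "': ",
                             conditionMessage(e))
                      })
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("no frames: TIFF has zero pages")
    frames <- lapply(pages, to_gray)
  } else {
    stop("path does not exist: ", path)
  }
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L) {
    stop("format error: frames have mixed dimensions")
  }
  image_sequence(frames, frame_interval = frame_interval,
                 pixel_size = pixel_size)
}

read_one_frame <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f)
  } else {
    p <- tiff::readTIFF(f, all = TRUE)
    if (is.list(p)) p[[1L]] else p
  }
  to_gray(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3L]),
                                               drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Write an image sequence as a multi-page 16-bit TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the global maximum before writing
#' (detection thresholds are response-map-relative, so the pipeline is
#' insensitive to this scaling).
#'
#' @param seq an [image_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  mx <- max(vapply(seq$frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(seq$frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Detections CSV round trip
#'
#' Columns `frame,x,y,scale,response,stage`; floating point, '.' decimal,
#' UTF-8, LF line endings.
#'
#' @param det detections data frame.
#' @param path CSV path.
#' @return `write_detections` returns `path` invisibly; `read_detections`
#'   returns the detections with their stage attribute restored.
#' @export
write_detections <- function(det, path) {
  out <- det
  out$stage <- detection_stage(det)
  if (is.null(out$stage)) out$stage <- "raw"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  stage <- if (nrow(df) > 0L) df$stage[1L] else "raw"
  new_detections(df$frame, df$x, df$y, df$scale, df$response, stage = stage)
}

#' Tracks CSV round trip
#'
#' Columns `track_id,frame,x,y,assigned` (filtered positions; `assigned` is
#' 1 when a detection was linked, 0 on a coasted frame).
#'
#' @param tracks a `bead_tracks` object.
#' @param path CSV path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` returns a
#'   `bead_tracks`-like list usable by [summarize_flow()].
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  utils::write.csv(df[, c("track_id", "frame", "x", "y", "assigned")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
                   eol = "\n")
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  trs <- lapply(split(df, df$track_id), function(s) {
    s <- s[order(s$frame), , drop = FALSE]
    list(id = s$track_id[1L],
         samples = data.frame(frame = s$frame, x = s$x, y = s$y,
                              det_x = NA_real_, det_y = NA_real_,
                              assigned = s$assigned),
         status = "terminated")
  })
  structure(unname(trs), class = "bead_tracks")
}

# FNV-1a 32-bit hash over the serialized object, reported as 8 hex digits.
# Used to stamp every artifact with the configuration that produced it.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0x811c9dc5
  for (b in bytes) {
    # XOR into the low byte (b < 256), arithmetic in doubles: h < 2^32
    # exceeds R's integer range
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # h * 16777619 mod 2^32
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

run_config_keys <- c(
  "radii", "sensitivity", "sensitivity_k", "suppression_radius",
  "heatmap_sigma", "heatmap_threshold", "cheb_link_dist",
  "max_stationary_frames", "process_noise", "measurement_noise",
  "gate_radius", "max_misses", "min_visible_frames",
  "pixel_size", "frame_interval", "seed")

#' Run configuration
#'
#' One document holding every pipeline parameter. Unknown keys are rejected
#' so a typo cannot silently fall back to a default. Round-trips losslessly
#' through YAML.
#'
#' @param ... overrides for any of: `radii`, `sensitivity`, `sensitivity_k`,
#'   `suppression_radius`, `heatmap_sigma`, `heatmap_threshold`,
#'   `cheb_link_dist`, `max_stationary_frames`, `process_noise` (length 4),
#'   `measurement_noise` (length 2), `gate_radius`, `max_misses`,
#'   `min_visible_frames`, `pixel_size`, `frame_interval`, `seed`.
#' @return A `run_config` list with all keys populated.
#' @export
run_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), run_config_keys)
  if (length(bad) > 0L) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  cfg <- list(radii = c(3, 4, 5), sensitivity = NULL, sensitivity_k = 5,
              suppression_radius = NULL, heatmap_sigma = 4,
              heatmap_threshold = NULL, cheb_link_dist = 2,
              max_stationary_frames = NULL,
              process_noise = c(0.5, 0.5, 1, 1),
              measurement_noise = c(0.25, 0.25),
              gate_radius = 10, max_misses = 3, min_visible_frames = 5,
              pixel_size = 1, frame_interval = 0.05, seed = 1L)
  cfg[names(over)] <- over
  if (any(cfg$radii <= 0)) stop("configuration rejected: non-positive radius")
  structure(cfg, class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline on one recording
#'
#' Reads (or accepts) an image sequence, detects and refines beads, tracks
#' them, summarizes the flow, and writes the artifacts: `detections.csv`,
#' `tracks.csv`, `summary.json` and a `manifest.json` carrying the
#' configuration, its hash, and the stage counts. Deterministic given the
#' configuration and input; rerunning yields byte-identical CSVs.
#'
#' @param input an [image_sequence()] or a path accepted by
#'   [read_sequence()].
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @return List with `detections`, `tracks`, `summary`, `config_hash`, and
#'   (when written) `paths`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seq <- if (inherits(input, "image_sequence")) input else {
    read_sequence(input, frame_interval = config$frame_interval,
                  pixel_size = config$pixel_size)
  }
  bank <- build_log_bank(config$radii, sensitivity = config$sensitivity,
                         sensitivity_k = config$sensitivity_k)
  refine <- refine_config(
    heatmap_sigma = config$heatmap_sigma,
    heatmap_threshold = config$heatmap_threshold,
    cheb_link_dist = config$cheb_link_dist,
    max_stationary_frames = config$max_stationary_frames)
  det <- withCallingHandlers(
    detect_sequence(seq, bank, refine,
                    suppression_radius = config$suppression_radius),
    error = function(e) stop("detection stage failed: ",
                             conditionMessage(e)))
  model <- kalman_model(process_noise = config$process_noise,
                        measurement_noise = config$measurement_noise)
  tcfg <- track_config(gate_radius = config$gate_radius,
                       max_misses = config$max_misses,
                       min_visible_frames = config$min_visible_frames)
  tracks <- tryCatch(
    track_sequence(det, model, tcfg, n_frames = n_frames(seq)),
    error = function(e) stop("tracking stage failed: ", conditionMessage(e)))
  summary <- if (length(tracks) > 0L) {
    summarize_flow(tracks, pixel_size = seq$pixel_size,
                   frame_interval = seq$frame_interval)
  } else NULL
  hash <- config_hash(unclass(config))
  result <- list(detections = det, tracks = tracks, summary = summary,
                 config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      detections = file.path(out_dir, "detections.csv"),
      tracks = file.path(out_dir, "tracks.csv"),
      summary = file.path(out_dir, "summary.json"),
      manifest = file.path(out_dir, "manifest.json"))
    write_detections(det, paths$detections)
    write_tracks(tracks, paths$tracks)
    sm <- if (is.null(summary)) list(n_tracks = 0L) else {
      list(n_tracks = summary$n_tracks, mean_speed = summary$mean_speed,
           direction = as.numeric(summary$direction),
           per_track_speed = as.numeric(summary$per_track_speed))
    }
    sm$config_hash <- hash
    jsonlite::write_json(sm, paths$summary, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config = Filter(Negate(is.null), unclass(config)),
           config_hash = hash,
           n_detections = nrow(det), n_tracks = length(tracks)),
      paths$manifest, auto_unbox = TRUE, digits = NA)
    result$paths <- paths
  }
  result
}

#' Batch pipeline over several recordings of one sample
#'
#' The assay records several rounds of bead release per whole-mount; this
#' concatenates their per-recording summaries.
#'
#' @param inputs list of inputs accepted by [run_pipeline()].
#' @param config a [run_config()].
#' @param out_dir parent output directory (one subdirectory per recording),
#'   or `NULL`.
#' @return List of per-recording results plus `pooled_speeds`, the
#'   concatenated per-track speeds across recordings.
#' @export
run_batch <- function(inputs, config = run_config(), out_dir = NULL) {
  res <- lapply(seq_along(inputs), function(i) {
    od <- if (is.null(out_dir)) NULL else {
      file.path(out_dir, sprintf("recording_%03d", i))
    }
    run_pipeline(inputs[[i]], config, od)
  })
  speeds <- unlist(lapply(res, function(r) {
    if (is.null(r$summary)) numeric(0) else r$summary$per_track_speed
  }))
  list(recordings = res, pooled_speeds = speeds)
}
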