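#' Construct an image sequence
#'
#' Container for a 2-D fluorescence time-lapse: a list of `H x W` intensity
#' matrices sharing one geometry, plus the acquisition metadata the physical
#' flow quantities depend on.
#'
#' @param frames list of numeric `H x W` matrices (all the same size,
#'   nonnegative finite intensities), or a single `T x H x W` array.
#' @param frame_interval seconds between consecutive frames (> 0). The bead
#'   assay this package targets acquires at 20 frames/s, i.e. 0.05 s.
#' @param pixel_size physical size of one pixel in micrometres (> 0).
#'
#' @return An object of class `image_sequence`: a list with elements
#'   `frames`, `frame_interval`, `pixel_size`.
#' @examples
#' seq <- image_sequence(list(matrix(0, 32, 32)), frame_interval = 0.05,
#'                       pixel_size = 0.5)
#' n_frames(seq)
#' @export
image_sequence <- function(frames, frame_interval = 0.05, pixel_size = 1) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1L]), function(t) frames[t, , ])
  }
  if (!is.list(frames) || length(frames) < 1L) {
    stop("'frames' must be a non-empty list of matrices or a T x H x W array")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("every frame must be a numeric matrix")
  }
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("all frames must share the same dimensions")
  ok <- vapply(frames, function(f) all(is.finite(f)) && all(f >= 0),
               logical(1))
  if (!all(ok)) stop("frame intensities must be finite and nonnegative")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0) {
    stop("'frame_interval' must be a single positive number (seconds)")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number (micrometres)")
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size),
    class = "image_sequence"
  )
}

#' @rdname image_sequence
#' @param x an `image_sequence`.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname image_sequence
#' @export
frame_dim <- function(x) dim(x$frames[[1L]])

#' @export
print.image_sequence <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf(
    "image_sequence: %d frames of %d x %d px, %.4g s/frame, %.4g um/px\n",
    n_frames(x), d[1L], d[2L], x$frame_interval, x$pixel_size))
  invisible(x)
}
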