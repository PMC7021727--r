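#' Multi-scale Laplacian-of-Gaussian filter bank
#'
#' Builds one LoG kernel per bead radius. For a bead of radius `r` pixels the
#' matched Gaussian width is `sigma = r / sqrt(2)`, and the kernel is
#' evaluated on the square support `i, j in [-ceiling(2 sigma),
#' ceiling(2 sigma)]` as
#'
#' \deqn{h(i,j) = \frac{(i^2 + j^2 - 2\sigma^2)\, g(i,j)}
#'                     {\sigma^4 \sum_m \sum_n g(m,n)},}
#'
#' with \eqn{g(i,j) = e^{-(i^2+j^2)/2\sigma^2}} the unnormalized Gaussian on
#' the same support. A bright bead on a dark background gives a negative
#' response at its center, so detections are response *minima*; the
#' sensitivity `tau` is a positive magnitude compared against `-response`.
#' No DC (zero-sum) correction is applied to the truncated kernel.
#'
#' @param radii bead radii in pixels (all > 0). The assay typically uses
#'   radii between 3 and 5 pixels for 1-um beads.
#' @param sensitivity response threshold `tau` (>= 0), or `NULL` to choose it
#'   per response map as `sensitivity_k` times the map's median absolute
#'   deviation. The interactive thresholding of the original workflow is
#'   replaced by this robust automatic default plus the explicit override.
#' @param sensitivity_k multiplier for the automatic MAD threshold.
#'
#' @return An object of class `log_bank`: list with `radii`, `sigmas`,
#'   `kernels` (one square odd-sided matrix per radius), `sensitivity`,
#'   `sensitivity_k`.
#' @examples
#' bank <- build_log_bank(c(3, 5))
#' sapply(bank$kernels, nrow)   # 11 and 17
#' bank$kernels[[1]][6, 6] < 0  # center entry is negative
#' @export
build_log_bank <- function(radii = c(3, 4, 5), sensitivity = NULL,
                           sensitivity_k = 5) {
  if (!is.numeric(radii) || length(radii) < 1L || any(!is.finite(radii)) ||
      any(radii <= 0)) {
    stop("'radii' must be positive finite numbers")
  }
  if (!is.null(sensitivity) &&
      (!is.numeric(sensitivity) || length(sensitivity) != 1L ||
       sensitivity < 0)) {
    stop("'sensitivity' must be NULL or a single nonnegative number")
  }
  radii <- sort(unique(as.numeric(radii)))
  sigmas <- radii / sqrt(2)
  kernels <- lapply(sigmas, log_kernel)
  structure(
    list(radii = radii, sigmas = sigmas, kernels = kernels,
         sensitivity = sensitivity, sensitivity_k = sensitivity_k),
    class = "log_bank"
  )
}

# LoG kernel on the support [-ceiling(2 sigma), ceiling(2 sigma)]^2.
# Matrix row index maps to i, column index to j; entry [i + w + 1, j + w + 1]
# holds h(i, j) where w is the half-width.
log_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  w <- ceiling(2 * sigma)
  idx <- -w:w
  r2 <- outer(idx^2, idx^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  (r2 - 2 * sigma^2) * g / (sigma^4 * sum(g))
}

#' @export
print.log_bank <- function(x, ...) {
  cat(sprintf("log_bank: radii {%s} px, kernel sides {%s}\n",
              paste(x$radii, collapse = ", "),
              paste(vapply(x$kernels, nrow, integer(1)), collapse = ", ")))
  if (is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity: auto (%g x MAD of each response map)\n",
                x$sensitivity_k))
  } else {
    cat(sprintf("  sensitivity: %g (fixed)\n", x$sensitivity))
  }
  invisible(x)
}
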