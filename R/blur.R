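#' Normalised 1-D Gaussian kernel
#'
#' Truncated at `ceiling(4 * sigma)` taps each side and normalised to unit
#' sum, so convolution preserves the mean intensity.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflect-pad a matrix by r rows/cols on each side (edge pixel not repeated,
# i.e. "symmetric about the boundary pixel": pad of c(a, b, c, ...) is
# (..., c, b | a, b, c, ...)). Requires r < min(dim).
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("blur radius too large for the frame")
  ri <- c((r + 1L):2L, seq_len(nr), (nr - 1L):(nr - r))
  ci <- c((r + 1L):2L, seq_len(nc), (nc - 1L):(nc - r))
  m[ri, ci]
}

#' Gaussian blur of a single frame
#'
#' Separable convolution with a truncated, normalised Gaussian kernel and
#' reflective boundary handling. This is the smoothing step that precedes
#' the frame-ratio computation in the change detector.
#'
#' @param frame numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix of identical dimensions.
#' @export
blur_frame <- function(frame, sigma) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  p <- reflect_pad(frame, r)
  nr <- nrow(frame); nc <- ncol(frame)
  # rows pass
  acc <- matrix(0, nr, ncol(p))
  for (j in seq_along(k))
    acc <- acc + k[j] * p[j:(j + nr - 1L), , drop = FALSE]
  # cols pass
  out <- matrix(0, nr, nc)
  for (j in seq_along(k))
    out <- out + k[j] * acc[, j:(j + nc - 1L), drop = FALSE]
  out
}

#' Gaussian blur of every frame of a movie
#'
#' The "radius" quoted for Gaussian blurs in common imaging software is the
#' standard deviation; `radius_px` is therefore used directly as sigma.
#'
#' @param movie a [movie_stack()].
#' @param radius_px Gaussian sigma in pixels (default 2, the detector's
#'   standard setting).
#' @return a `movie_stack` of identical dimensions and calibration.
#' @export
blur_stack <- function(movie, radius_px = 2) {
  stopifnot(inherits(movie, "movie_stack"), radius_px > 0)
  out <- movie$frames
  for (t in seq_len(n_frames(movie)))
    out[t, , ] <- blur_frame(movie$frames[t, , ], radius_px)
  movie_stack(out, movie$pixel_size_um, movie$frame_interval_s)
}
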