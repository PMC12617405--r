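#' Calibrated time-lapse movie stack
#'
#' A `movie_stack` bundles a T x H x W intensity array with its spatial and
#' temporal calibration. It is the unit of analysis for the gliding-assay
#' pipeline: segmentation, tracking and event detection all consume it.
#' Intensities are arbitrary nonnegative units (any integer or float
#' grayscale camera output is accepted); calibration is always supplied by
#' the caller, never read from file metadata.
#'
#' @param frames numeric array with dimensions time x rows x cols, all
#'   values finite and >= 0.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s time between consecutive frames in seconds (> 0).
#' @return an object of class `movie_stack` with fields `frames`,
#'   `pixel_size_um`, `frame_interval_s`.
#' @examples
#' m <- movie_stack(array(1, c(3, 8, 8)), pixel_size_um = 0.1,
#'                  frame_interval_s = 1)
#' n_frames(m)
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time x rows x cols)")
  if (!all(is.finite(frames)))
    stop("movie intensities must all be finite")
  if (any(frames < 0))
    stop("movie intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  structure(
    list(frames = frames,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s)),
    class = "movie_stack")
}

#' @rdname movie_stack
#' @param x a `movie_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "movie_stack"))
  dim(x$frames)[1L]
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "movie_stack: %d frames of %d x %d px (%.4g um/px, %.4g s/frame)\n",
    d[1L], d[2L], d[3L], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Get one frame of a movie as a matrix
#'
#' @param movie a `movie_stack`.
#' @param i 0-based frame index (the convention used throughout: frames,
#'   rows and columns are all 0-based in reported coordinates).
#' @return H x W numeric matrix.
#' @export
get_frame <- function(movie, i) {
  stopifnot(inherits(movie, "movie_stack"))
  ti <- as.integer(i) + 1L
  if (ti < 1L || ti > n_frames(movie)) stop("frame index out of range")
  movie$frames[ti, , ]
}

#' Read a multi-page grayscale TIFF as a movie stack
#'
#' Pages become frames in order. Calibration is taken from the arguments
#' (TIFF tag dialects are too unreliable to trust for reproducible
#' analysis); any resolution tags in the file are ignored.
#'
#' @param path path to a readable multi-page grayscale TIFF.
#' @inheritParams movie_stack
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_s) {
  if (!file.exists(path))
    stop(sprintf("cannot read movie: no such file '%s'", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e)
      stop(sprintf("cannot read movie '%s': %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop(sprintf("'%s' has %d page(s); a movie needs at least 2", path,
                 length(pages)))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L))))
    stop(sprintf("'%s' is not single-channel grayscale", path))
  d <- dim(pages[[1L]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1L))))
    stop(sprintf("'%s' has pages of differing dimensions", path))
  frames <- array(0, c(length(pages), d[1L], d[2L]))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  movie_stack(frames, pixel_size_um, frame_interval_s)
}

#' Write a movie stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and clipped to the 16-bit range, so
#' `read_movie(write_movie(m))` reproduces integer-valued stacks exactly.
#'
#' @param movie a `movie_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  mx <- 65535
  pages <- lapply(seq_len(n_frames(movie)), function(t) {
    m <- pmin(pmax(round(movie$frames[t, , ]), 0), mx)
    m / mx  # tiff writes [0,1] scaled to the sample depth
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE),
    error = function(e)
      stop(sprintf("cannot write movie '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Write flat records to CSV
#'
#' Records (a data frame, or a list of same-named lists) are written with a
#' header row and full float precision (>= 6 significant digits are
#' preserved; we write at R's default 15 digits). An empty record set
#' produces a header-only file when the field set is known.
#'
#' @param records data.frame, or list of named lists sharing one field set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L)
      stop("an empty list has no field set; pass a 0-row data.frame instead")
    fields <- names(records[[1L]])
    if (is.null(fields) || any(!vapply(
          records, function(r) identical(names(r), fields), logical(1L))))
      stop("records must share a single named field set")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else stop("`records` must be a data.frame or list of named lists")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write table '%s': %s", path, conditionMessage(e))))
  on.exit(close(con))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read table: no such file '%s'", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
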