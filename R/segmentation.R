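# Per-frame filament segmentation and measurement.
#
# Filaments are separated from background by deterministic thresholding of
# the smoothed frame (k SDs above a robust background estimate by default,
# or Otsu); connected components above a minimum area become labelled
# filaments. Background statistics — the inputs to the event-detection
# threshold — are computed over label-0 pixels only and pooled per movie.

#' Segmentation parameters
#'
#' @param blur_sigma_px pre-smoothing Gaussian sigma (>= 0; 0 = none).
#' @param threshold_method "k_sigma" (default: background + k_sigma x
#'   background SD of the smoothed frame, seeded robustly from the frame
#'   median and MAD so filament pixels do not bias it) or "otsu". The
#'   robust method is the default because Otsu's threshold splits the
#'   noise distribution on frames with little or no foreground — the
#'   normal case in a sparse assay — which corrupts the background
#'   statistics the event threshold depends on.
#' @param k_sigma multiples of background SD above background mean.
#' @param min_area_px smallest accepted object, pixels.
#' @return validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(blur_sigma_px = 1,
                                threshold_method = c("k_sigma", "otsu"),
                                k_sigma = 4, min_area_px = 10L) {
  threshold_method <- match.arg(threshold_method)
  if (blur_sigma_px < 0) stop("blur_sigma_px must be >= 0")
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (min_area_px < 1L) stop("min_area_px must be >= 1")
  structure(list(blur_sigma_px = blur_sigma_px,
                 threshold_method = threshold_method,
                 k_sigma = k_sigma,
                 min_area_px = as.integer(min_area_px)),
            class = "segmentation_params")
}

# Otsu threshold on a numeric matrix (256-bin histogram between min/max).
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)   # constant frame: nothing above
  e <- EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
  as.numeric(e)
}

#' Segment one frame into labelled filaments and background
#'
#' The frame is smoothed, thresholded, and connected components (8-neighbour)
#' of at least `min_area_px` pixels are labelled 1..K; everything else is
#' background. Background mean/SD are computed over label-0 pixels of the
#' original (unsmoothed) frame. A constant frame yields zero filaments.
#'
#' @param frame numeric matrix (finite).
#' @param params [segmentation_params()].
#' @return list of class `labeled_frame`: `labels` (integer matrix, 0 =
#'   background), `n` (number of filaments), `background_mean`,
#'   `background_sd`, `threshold`.
#' @export
segment_frame <- function(frame, params = segmentation_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)),
            inherits(params, "segmentation_params"))
  sm <- if (params$blur_sigma_px > 0)
    blur_frame(frame, params$blur_sigma_px) else frame
  thr <- switch(params$threshold_method,
    otsu = otsu_threshold(sm),
    k_sigma = {
      bg_mu <- stats::median(sm)
      bg_sd <- stats::mad(sm)   # 1.4826 * MAD, robust to filament pixels
      bg_mu + params$k_sigma * bg_sd
    })
  mask <- sm > thr
  labels <- matrix(0L, nrow(frame), ncol(frame))
  if (any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(frame))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= params$min_area_px)
    if (length(keep)) {
      relab <- integer(length(sizes))
      relab[keep] <- seq_along(keep)
      pos <- lab > 0L
      labels[pos] <- relab[lab[pos]]
    }
  }
  bgpix <- frame[labels == 0L]
  if (length(bgpix) == 0L)
    stop("degenerate segmentation: no background pixels found")
  structure(list(labels = labels, n = max(labels),
                 background_mean = mean(bgpix),
                 background_sd = if (length(bgpix) > 1L)
                   stats::sd(bgpix) else 0,
                 threshold = thr),
            class = "labeled_frame")
}

# --- skeletonization ------------------------------------------------------

# Zhang-Suen thinning of a logical mask; returns a 1-px-wide skeleton.
zhang_suen_thin <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- (1L + max(0L, dr)):(nr + min(0L, dr))
    cs <- (1L + max(0L, dc)):(nc + min(0L, dc))
    out[rs - dr, cs - dc] <- x[rs, cs]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- sh(m, -1L, 0L); p3 <- sh(m, -1L, 1L); p4 <- sh(m, 0L, 1L)
      p5 <- sh(m, 1L, 1L);  p6 <- sh(m, 1L, 0L);  p7 <- sh(m, 1L, -1L)
      p8 <- sh(m, 0L, -1L); p9 <- sh(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1L) {
        c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE] == 1L
}

# Geodesic diameter of a skeleton mask: the longest shortest path over the
# 8-connected pixel graph with step weights 1 / sqrt(2), plus the pixels
# (row, col) attaining it. A single pixel has length 0.
skeleton_geodesic <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(list(length = 0, ends = NULL))
  if (n == 1L) return(list(length = 0, ends = pts[c(1L, 1L), , drop = FALSE]))
  d2 <- as.matrix(stats::dist(pts))
  adj <- which(d2 > 0 & d2 < 1.5, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  if (nrow(adj) == 0L)
    return(list(length = 0, ends = pts[c(1L, 1L), , drop = FALSE]))
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  igraph::E(g)$weight <- d2[adj]
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  dm <- igraph::distances(g)
  dm[!is.finite(dm)] <- 0
  ij <- arrayInd(which.max(dm), dim(dm))
  list(length = max(dm), ends = pts[as.vector(ij), , drop = FALSE])
}

# Skeleton length of a mask: geodesic diameter of its thinned skeleton.
# Thinning erodes rounded/tapered ends by roughly the mask half-width
# while thresholding extends the mask slightly beyond the true object, so
# the estimate is close to unbiased for thin masks and increasingly short
# for masks much wider than the object (see the methods vignette).
mask_skeleton_length <- function(mask) {
  skeleton_geodesic(zhang_suen_thin(mask))$length
}

#' Measure labelled filaments
#'
#' One measure per label: unweighted mask centroid (0-based px), area, and
#' skeleton length — the geodesic path length of the morphological skeleton
#' (unit steps 1, diagonal steps sqrt(2)) times the pixel size.
#'
#' @param lf a `labeled_frame` from [segment_frame()].
#' @param pixel_size_um micrometres per pixel.
#' @param frame_index 0-based frame index recorded in the output.
#' @return data.frame: frame, label, row_px, col_px, area_px, length_um.
#' @export
measure_filaments <- function(lf, pixel_size_um, frame_index = 0L) {
  stopifnot(inherits(lf, "labeled_frame"), pixel_size_um > 0)
  K <- lf$n
  out <- data.frame(frame = integer(0), label = integer(0),
                    row_px = numeric(0), col_px = numeric(0),
                    area_px = integer(0), length_um = numeric(0))
  if (K == 0L) return(out)
  for (k in seq_len(K)) {
    pix <- which(lf$labels == k, arr.ind = TRUE)
    # thin on the bounding box only (thinning cost scales with the crop)
    r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
    c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
    crop <- lf$labels[r0:r1, c0:c1, drop = FALSE] == k
    len_px <- mask_skeleton_length(crop)
    out <- rbind(out, data.frame(
      frame = as.integer(frame_index), label = k,
      row_px = mean(pix[, 1]) - 1, col_px = mean(pix[, 2]) - 1,
      area_px = nrow(pix), length_um = len_px * pixel_size_um))
  }
  out
}

#' Segment every frame of a movie
#'
#' @param movie a [movie_stack()].
#' @param params [segmentation_params()].
#' @return list with `measures` (one data.frame over all frames) and
#'   `frames` (list of `labeled_frame`s).
#' @export
segment_movie <- function(movie, params = segmentation_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  lfs <- lapply(seq_len(n_frames(movie)) - 1L, function(t)
    segment_frame(get_frame(movie, t), params))
  measures <- do.call(rbind, lapply(seq_along(lfs), function(i)
    measure_filaments(lfs[[i]], movie$pixel_size_um, i - 1L)))
  list(measures = measures, frames = lfs)
}

#' Pooled background statistics of a movie
#'
#' Segmentation is applied per frame; the mean and SD are computed over the
#' background (label-0) pixels of all frames pooled — one pair per movie.
#' These are the inputs to [event_threshold()].
#'
#' @param movie a [movie_stack()].
#' @param params [segmentation_params()].
#' @return named list: background_mean, background_sd, n_pixels.
#' @export
background_stats <- function(movie, params = segmentation_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  vals <- unlist(lapply(seq_len(n_frames(movie)) - 1L, function(t) {
    lf <- segment_frame(get_frame(movie, t), params)
    get_frame(movie, t)[lf$labels == 0L]
  }))
  if (length(vals) == 0L)
    stop("degenerate segmentation: no background pixels in any frame")
  list(background_mean = mean(vals),
       background_sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n_pixels = length(vals))
}
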