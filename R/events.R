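# Frame-ratio change detection of filament detachment and wobbling.
#
# The detector Gaussian-blurs each frame, forms the stack of per-pixel
# ratios of consecutive frames, and flags connected spots whose ratio
# exceeds a background-derived cutoff 1 + k * (SD/mean of the background).
# Under pure-background fluctuation the ratio stays within a few relative
# noise widths of 1, so a supra-threshold spot marks a pixel neighbourhood
# that genuinely brightened — a filament that appeared (wobble landing
# site) or, with the two-sided option, vanished (detachment).

#' Event-detection parameters
#'
#' @param blur_radius_px Gaussian blur sigma applied to each frame before
#'   ratioing (default 2 px).
#' @param threshold_k multiplier k in the cutoff 1 + k * (SD/mean)
#'   (default 4).
#' @param min_spot_area_px smallest accepted supra-threshold spot.
#' @param merge_radius_px,merge_frames spots in ratio-frames at most
#'   `merge_frames` apart with centroids within `merge_radius_px` are
#'   merged into one event (one physical event can exceed threshold in two
#'   successive ratios).
#' @param display_lo,display_hi linear display range for the temporal
#'   max-projection rendering (defaults 1.3 and 3.0).
#' @param epsilon denominator guard added to both blurred frames before
#'   dividing; NULL (default) uses 1e-6 x the movie median, 0 disables it.
#' @param two_sided if TRUE, 1/ratio is tested against the same cutoff as
#'   well, so disappearance-dominant detachments (the filament vanishes
#'   and no pixel brightens) are also detected. Default FALSE: only
#'   brightening pixels trigger events, matching the one-sided display
#'   convention.
#' @return validated list of class `event_params`.
#' @export
event_params <- function(blur_radius_px = 2, threshold_k = 4,
                         min_spot_area_px = 4L, merge_radius_px = 5,
                         merge_frames = 1L, display_lo = 1.3,
                         display_hi = 3.0, epsilon = NULL,
                         two_sided = FALSE) {
  if (blur_radius_px <= 0) stop("blur_radius_px must be > 0")
  if (threshold_k <= 0) stop("threshold_k must be > 0")
  if (min_spot_area_px < 1L) stop("min_spot_area_px must be >= 1")
  if (merge_radius_px < 0 || merge_frames < 0L)
    stop("merge parameters must be >= 0")
  if (display_lo >= display_hi) stop("display_lo must be < display_hi")
  if (!is.null(epsilon) && epsilon < 0) stop("epsilon must be >= 0")
  structure(list(blur_radius_px = blur_radius_px, threshold_k = threshold_k,
                 min_spot_area_px = as.integer(min_spot_area_px),
                 merge_radius_px = merge_radius_px,
                 merge_frames = as.integer(merge_frames),
                 display_lo = display_lo, display_hi = display_hi,
                 epsilon = epsilon, two_sided = isTRUE(two_sided)),
            class = "event_params")
}

#' Stack of consecutive-frame intensity ratios
#'
#' Ratio-frame i (0-based) is (blurred frame i+1 + eps) / (blurred frame i
#' + eps). A small epsilon guards against zero denominators without
#' perturbing ratios at realistic background levels.
#'
#' @param movie a [movie_stack()] with at least 2 frames.
#' @param params [event_params()].
#' @return list of class `ratio_stack`: `ratios` ((T-1) x H x W array),
#'   `pixel_size_um`, `frame_interval_s`, `epsilon`.
#' @export
ratio_stack <- function(movie, params = event_params()) {
  stopifnot(inherits(movie, "movie_stack"),
            inherits(params, "event_params"))
  Tn <- n_frames(movie)
  if (Tn < 2L) stop("ratio analysis needs at least 2 frames")
  eps <- if (is.null(params$epsilon))
    1e-6 * stats::median(movie$frames) else params$epsilon
  b <- blur_stack(movie, params$blur_radius_px)
  d <- dim(movie$frames)
  ratios <- array(0, c(Tn - 1L, d[2L], d[3L]))
  for (i in seq_len(Tn - 1L)) {
    r <- (b$frames[i + 1L, , ] + eps) / (b$frames[i, , ] + eps)
    if (!all(is.finite(r)))
      stop(sprintf("nonfinite ratio at ratio-frame %d", i - 1L))
    ratios[i, , ] <- r
  }
  structure(list(ratios = ratios, pixel_size_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s, epsilon = eps),
            class = "ratio_stack")
}

#' Background-derived ratio threshold
#'
#' The cutoff above which a frame-to-frame intensity ratio is scored as a
#' detachment/wobbling event: 1 + k * (background SD / background mean).
#' A background with zero SD gives 1, so any above-unity ratio is
#' supra-threshold.
#'
#' @param background_mean,background_sd pooled per-movie background
#'   statistics (see [background_stats()]).
#' @param threshold_k multiplier k (default 4).
#' @return the ratio threshold.
#' @examples
#' event_threshold(100, 5, 4)  # 1.2
#' @export
event_threshold <- function(background_mean, background_sd,
                            threshold_k = 4) {
  if (background_mean <= 0)
    stop("background_mean must be > 0")
  if (background_sd < 0)
    stop("background_sd must be >= 0")
  1 + threshold_k * (background_sd / background_mean)
}

# Connected supra-threshold spots of one ratio frame. One physical event
# (a vanished or landed filament) often crosses the threshold in noise-
# broken fragments along the filament, so the mask is morphologically
# closed over merge_radius_px before labelling; areas, centroids and peaks
# are computed over the original supra-threshold pixels of each component.
frame_spots <- function(rmat, threshold, params) {
  mask <- rmat > threshold
  if (params$two_sided) mask <- mask | (rmat < 1 / threshold)
  if (!any(mask)) return(NULL)
  lab_src <- mask
  if (params$merge_radius_px >= 1) {
    kern <- EBImage::makeBrush(2L * floor(params$merge_radius_px) + 1L,
                               shape = "disc")
    lab_src <- EBImage::closing(EBImage::Image(mask * 1), kern) > 0
  }
  lab <- EBImage::bwlabel(EBImage::Image(lab_src * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(rmat))
  lab[!mask] <- 0L
  K <- max(lab)
  rows <- list()
  for (k in seq_len(K)) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) < params$min_spot_area_px) next
    vals <- rmat[pix]
    mag <- pmax(vals, 1 / vals)
    # centroid weighted by ratio-change magnitude: localises the event
    # better than the unweighted footprint when the region is asymmetric
    wt <- mag - 1
    rows[[length(rows) + 1L]] <- data.frame(
      row_px = sum(pix[, 1] * wt) / sum(wt) - 1,
      col_px = sum(pix[, 2] * wt) / sum(wt) - 1,
      area_px = nrow(pix), peak_ratio = max(mag))
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Detect detachment/wobbling events in a ratio stack
#'
#' Per ratio-frame, connected components of supra-threshold pixels with at
#' least `min_spot_area_px` pixels become candidate spots; candidates in
#' ratio-frames at most `merge_frames` apart with centroids within
#' `merge_radius_px` are merged into one event (the earliest frame and its
#' centroid are kept; area is the maximum, peak ratio the maximum). Events
#' are returned sorted by frame, then row, then column.
#'
#' @param rs a [ratio_stack()].
#' @param threshold ratio cutoff from [event_threshold()] (> 1).
#' @param params [event_params()].
#' @return data.frame: frame (0-based ratio-frame index: the event occurred
#'   between source frames `frame` and `frame + 1`), row_px, col_px,
#'   area_px, peak_ratio, n_merged, type (always "unclassified": wobbling
#'   and detachment are pooled, not distinguished).
#' @export
detect_events <- function(rs, threshold, params = event_params()) {
  stopifnot(inherits(rs, "ratio_stack"), inherits(params, "event_params"))
  if (threshold <= 1) stop("threshold must be > 1")
  Tn <- dim(rs$ratios)[1L]
  cand <- list()
  for (i in seq_len(Tn)) {
    sp <- frame_spots(rs$ratios[i, , ], threshold, params)
    if (!is.null(sp)) { sp$frame <- i - 1L; cand[[length(cand) + 1L]] <- sp }
  }
  empty <- data.frame(frame = integer(0), row_px = numeric(0),
                      col_px = numeric(0), area_px = integer(0),
                      peak_ratio = numeric(0), n_merged = integer(0),
                      type = character(0))
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)

  # union-find merge of nearby candidates in nearby ratio-frames
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      if (abs(cand$frame[a] - cand$frame[b]) > params$merge_frames) next
      dd <- sqrt((cand$row_px[a] - cand$row_px[b])^2 +
                 (cand$col_px[a] - cand$col_px[b])^2)
      if (dd <= params$merge_radius_px) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    g <- cand[roots == r, , drop = FALSE]
    first <- which.min(g$frame)
    data.frame(frame = g$frame[first], row_px = g$row_px[first],
               col_px = g$col_px[first],
               area_px = as.integer(max(g$area_px)),
               peak_ratio = max(g$peak_ratio),
               n_merged = nrow(g), type = "unclassified")
  }))
  out <- out[order(out$frame, out$row_px, out$col_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full event-detection pipeline on a movie
#'
#' Convenience wrapper: background statistics (from segmentation of the
#' original movie), threshold, ratio stack, and event detection.
#'
#' @param movie a [movie_stack()].
#' @param params [event_params()].
#' @param seg_params [segmentation_params()] for the background estimate.
#' @return list: events, threshold, background (list), ratio_stack.
#' @export
detect_movie_events <- function(movie, params = event_params(),
                                seg_params = segmentation_params()) {
  bg <- background_stats(movie, seg_params)
  thr <- event_threshold(bg$background_mean, bg$background_sd,
                         params$threshold_k)
  rs <- ratio_stack(movie, params)
  ev <- detect_events(rs, thr, params)
  list(events = ev, threshold = thr, background = bg, ratio_stack = rs)
}

#' Temporal maximum projection of a ratio stack
#'
#' Per-pixel maximum over all ratio-frames; the rendering clips to
#' [display_lo, display_hi] and maps through a black-red-yellow-white
#' ("fire"-like) pseudocolour ramp. Optionally writes a PNG.
#'
#' @param rs a [ratio_stack()].
#' @param display_lo,display_hi linear display range (defaults 1.3, 3.0).
#' @param png_path optional path; if given, the rendering is written there.
#' @return list: `projection` (matrix), `rgb` (H x W x 3 array in [0,1]).
#' @export
temporal_max_projection <- function(rs, display_lo = 1.3, display_hi = 3.0,
                                    png_path = NULL) {
  stopifnot(inherits(rs, "ratio_stack"), display_lo < display_hi)
  proj <- apply(rs$ratios, c(2L, 3L), max)
  z <- pmin(pmax((proj - display_lo) / (display_hi - display_lo), 0), 1)
  # piecewise-linear fire-like ramp: black -> red -> yellow -> white
  r <- pmin(3 * z, 1)
  g <- pmin(pmax(3 * z - 1, 0), 1)
  b <- pmin(pmax(3 * z - 2, 0), 1)
  rgb <- array(c(r, g, b), c(nrow(proj), ncol(proj), 3L))
  if (!is.null(png_path)) png::writePNG(rgb, png_path)
  list(projection = proj, rgb = rgb)
}

#' Assign events to tracks and compute the per-filament event frequency
#'
#' Each event is assigned to the track whose position at the event's source
#' frame (or the nearest tracked frame) is closest, if within `max_disp_um`;
#' otherwise it stays unassigned. The movie-level frequency of
#' detachment/wobbling per filament is assigned events / number of tracks.
#'
#' @param events data.frame from [detect_events()].
#' @param tracks data.frame from [link_tracks()] on the same movie.
#' @param pixel_size_um micrometres per pixel.
#' @param max_disp_um maximum event-to-track distance for assignment.
#' @return list: `events` (with a track_id column, NA when unassigned),
#'   `per_track` (track_id, n_events), `frequency` (assigned events /
#'   n_tracks), `n_unassigned`.
#' @export
events_per_filament <- function(events, tracks, pixel_size_um,
                                max_disp_um = 2) {
  ids <- unique(tracks$track_id)
  n_tracks <- length(ids)
  track_id <- rep(NA_integer_, nrow(events))
  if (nrow(events) && n_tracks) {
    max_px <- max_disp_um / pixel_size_um
    for (e in seq_len(nrow(events))) {
      src <- events$frame[e]   # event between source frames src and src+1
      best <- NA_integer_; bestd <- Inf
      for (id in ids) {
        p <- tracks[tracks$track_id == id, , drop = FALSE]
        k <- which.min(abs(p$frame - src))
        dd <- sqrt((p$row_px[k] - events$row_px[e])^2 +
                   (p$col_px[k] - events$col_px[e])^2)
        if (dd < bestd) { bestd <- dd; best <- id }
      }
      if (is.finite(bestd) && bestd <= max_px) track_id[e] <- best
    }
  }
  events$track_id <- track_id
  per_track <- data.frame(
    track_id = ids,
    n_events = vapply(ids, function(id)
      sum(!is.na(track_id) & track_id == id), integer(1L)))
  list(events = events,
       per_track = per_track,
       frequency = if (n_tracks) sum(!is.na(track_id)) / n_tracks else
         NA_real_,
       n_unassigned = sum(is.na(track_id)))
}
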