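# Frame-to-frame linking of filament measures into tracks, and the
# per-movie motility summary (filament counts, moving fraction, gliding
# speed of moving filaments).

#' Tracking parameters
#'
#' Filament densities in surface motility assays are low, so linking is a
#' deterministic greedy globally-nearest-pair assignment; the "moving"
#' classification uses a dual criterion (mean speed AND net displacement)
#' to exclude stationary filaments whose centroids jitter with noise.
#'
#' @param max_disp_um maximum centroid displacement between consecutive
#'   frames for a link.
#' @param max_gap frames a track may go unmatched before it is closed.
#' @param min_track_len minimum number of points for a reported track.
#' @param moving_speed_threshold_um_per_s minimum mean speed of a "moving"
#'   filament (default 0.05 um/s).
#' @param moving_net_disp_um minimum net displacement of a "moving"
#'   filament (default 0.5 um).
#' @return validated list of class `tracking_params`.
#' @export
tracking_params <- function(max_disp_um = 2.0, max_gap = 1L,
                            min_track_len = 5L,
                            moving_speed_threshold_um_per_s = 0.05,
                            moving_net_disp_um = 0.5) {
  if (max_disp_um <= 0) stop("max_disp_um must be > 0")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (min_track_len < 2L) stop("min_track_len must be >= 2")
  if (moving_speed_threshold_um_per_s < 0 || moving_net_disp_um < 0)
    stop("moving thresholds must be >= 0")
  structure(list(max_disp_um = max_disp_um, max_gap = as.integer(max_gap),
                 min_track_len = as.integer(min_track_len),
                 moving_speed_threshold_um_per_s =
                   moving_speed_threshold_um_per_s,
                 moving_net_disp_um = moving_net_disp_um),
            class = "tracking_params")
}

#' Link per-frame filament measures into tracks
#'
#' Greedy globally-nearest-pair linking: at each frame transition the
#' closest (open track, new measure) pair within `max_disp_um` is linked
#' first, then the next closest among the remainder, and so on. Unmatched
#' measures open new tracks; tracks unmatched for more than `max_gap`
#' frames are closed. Ties are broken deterministically by lower label.
#'
#' @param measures data.frame from [segment_movie()] (frame, label, row_px,
#'   col_px, area_px, length_um), ordered by frame.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s seconds per frame.
#' @param params [tracking_params()].
#' @return data.frame of track points: track_id, frame, row_px, col_px,
#'   length_um. Tracks shorter than `min_track_len` are discarded and ids
#'   renumbered consecutively.
#' @export
link_tracks <- function(measures, pixel_size_um, frame_interval_s,
                        params = tracking_params()) {
  stopifnot(inherits(params, "tracking_params"), pixel_size_um > 0)
  cols <- c("frame", "label", "row_px", "col_px", "length_um")
  if (!all(cols %in% names(measures)))
    stop("measures must have columns: ", paste(cols, collapse = ", "))
  if (nrow(measures) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      row_px = numeric(0), col_px = numeric(0),
                      length_um = numeric(0)))
  measures <- measures[order(measures$frame, measures$label), , drop = FALSE]
  max_disp_px <- params$max_disp_um / pixel_size_um

  open <- list()   # each: list(id, last_frame, row, col, points = list())
  closed <- list()
  next_id <- 1L
  for (t in sort(unique(measures$frame))) {
    mt <- measures[measures$frame == t, , drop = FALSE]
    # close stale tracks
    if (length(open)) {
      stale <- vapply(open, function(o) t - o$last_frame > params$max_gap + 1L,
                      logical(1L))
      closed <- c(closed, open[stale])
      open <- open[!stale]
    }
    assigned_m <- rep(FALSE, nrow(mt))
    assigned_o <- rep(FALSE, length(open))
    if (length(open) && nrow(mt)) {
      orow <- vapply(open, `[[`, numeric(1L), "row")
      ocol <- vapply(open, `[[`, numeric(1L), "col")
      d <- sqrt(outer(orow, mt$row_px, "-")^2 +
                outer(ocol, mt$col_px, "-")^2)
      repeat {
        d2 <- d
        d2[assigned_o, ] <- Inf
        d2[, assigned_m] <- Inf
        if (all(!is.finite(d2)) || min(d2) > max_disp_px) break
        # ties: which.min scans column-major, i.e. lower open-track index
        # first, then lower (label-ordered) measure index
        ij <- arrayInd(which.min(d2), dim(d2))
        oi <- ij[1L]; mi <- ij[2L]
        open[[oi]]$points[[length(open[[oi]]$points) + 1L]] <-
          mt[mi, , drop = FALSE]
        open[[oi]]$last_frame <- t
        open[[oi]]$row <- mt$row_px[mi]; open[[oi]]$col <- mt$col_px[mi]
        assigned_o[oi] <- TRUE; assigned_m[mi] <- TRUE
      }
    }
    for (mi in which(!assigned_m)) {
      open[[length(open) + 1L]] <- list(
        id = next_id, last_frame = t,
        row = mt$row_px[mi], col = mt$col_px[mi],
        points = list(mt[mi, , drop = FALSE]))
      next_id <- next_id + 1L
    }
  }
  closed <- c(closed, open)
  keep <- Filter(function(o) length(o$points) >= params$min_track_len,
                 closed)
  if (length(keep) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      row_px = numeric(0), col_px = numeric(0),
                      length_um = numeric(0)))
  keep <- keep[order(vapply(keep, `[[`, integer(1L), "id"))]
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    pts <- do.call(rbind, keep[[i]]$points)
    data.frame(track_id = i, frame = pts$frame, row_px = pts$row_px,
               col_px = pts$col_px, length_um = pts$length_um)
  }))
  rownames(out) <- NULL
  out
}

track_points <- function(tracks, id) {
  p <- tracks[tracks$track_id == id, , drop = FALSE]
  p[order(p$frame), , drop = FALSE]
}

#' Mean frame-to-frame speed of one track
#'
#' Mean over consecutive point pairs of centroid displacement divided by
#' the actual elapsed time (so gaps contribute their true duration).
#'
#' @param track data.frame of one track's points (frame, row_px, col_px).
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s seconds per frame.
#' @return speed in um/s.
#' @export
track_speed <- function(track, pixel_size_um, frame_interval_s) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L)
    stop("speed is undefined for a track with fewer than 2 points")
  disp_px <- sqrt(diff(track$row_px)^2 + diff(track$col_px)^2)
  dt_s <- diff(track$frame) * frame_interval_s
  mean(disp_px * pixel_size_um / dt_s)
}

#' Net displacement of one track
#' @inheritParams track_speed
#' @return first-to-last centroid distance, um.
#' @export
track_net_displacement <- function(track, pixel_size_um) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  sqrt((track$row_px[n] - track$row_px[1])^2 +
       (track$col_px[n] - track$col_px[1])^2) * pixel_size_um
}

#' Classify a track as moving
#'
#' TRUE iff mean speed exceeds `moving_speed_threshold_um_per_s` AND net
#' displacement exceeds `moving_net_disp_um` — the dual criterion excludes
#' stationary filaments whose centroids jitter.
#'
#' @inheritParams track_speed
#' @param params [tracking_params()].
#' @return logical.
#' @export
classify_moving <- function(track, pixel_size_um, frame_interval_s,
                            params = tracking_params()) {
  sp <- track_speed(track, pixel_size_um, frame_interval_s)
  nd <- track_net_displacement(track, pixel_size_um)
  sp > params$moving_speed_threshold_um_per_s &&
    nd > params$moving_net_disp_um
}

#' Per-movie motility summary
#'
#' Reports both definitions of "filaments per movie": the mean per-frame
#' segmented object count (landed filaments), rounded, and the number of
#' tracks — the two need not agree and conflating them is a common source
#' of confusion. Percent moving and mean speed are over tracks; the
#' detachment/wobbling frequency is filled in by [events_per_filament()].
#'
#' @param tracks data.frame from [link_tracks()].
#' @param measures per-frame measures (for the per-frame count).
#' @param pixel_size_um,frame_interval_s movie calibration.
#' @param params [tracking_params()].
#' @param movie_id identifier recorded in the summary.
#' @return one-row data.frame: movie_id, n_filaments (mean per-frame count,
#'   rounded), n_tracks, percent_moving, mean_speed_moving_um_per_s,
#'   events_per_filament (NA until events are assigned). With zero tracks
#'   the motility fields are NA.
#' @export
summarize_motility <- function(tracks, measures, pixel_size_um,
                               frame_interval_s,
                               params = tracking_params(),
                               movie_id = "movie") {
  n_frames_seen <- length(unique(measures$frame))
  n_fil <- if (n_frames_seen > 0L)
    as.integer(round(nrow(measures) / n_frames_seen)) else 0L
  ids <- unique(tracks$track_id)
  if (length(ids) == 0L)
    return(data.frame(movie_id = movie_id, n_filaments = n_fil,
                      n_tracks = 0L, percent_moving = NA_real_,
                      mean_speed_moving_um_per_s = NA_real_,
                      events_per_filament = NA_real_))
  moving <- vapply(ids, function(id)
    classify_moving(track_points(tracks, id), pixel_size_um,
                    frame_interval_s, params), logical(1L))
  speeds <- vapply(ids, function(id)
    track_speed(track_points(tracks, id), pixel_size_um,
                frame_interval_s), numeric(1L))
  data.frame(
    movie_id = movie_id, n_filaments = n_fil, n_tracks = length(ids),
    percent_moving = 100 * sum(moving) / length(ids),
    mean_speed_moving_um_per_s =
      if (any(moving)) mean(speeds[moving]) else NA_real_,
    events_per_filament = NA_real_)
}
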