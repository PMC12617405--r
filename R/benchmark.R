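# Ground-truth benchmarks of the event detector on simulated movies.

#' Match detected events against simulator ground truth
#'
#' A detection matches a true event when its (merged) window covers the
#' event — the source-frame change lies within `match_frames` of the true
#' event frame — and its centroid lies within `match_radius_px` of the
#' filament's pre-event or post-event position (a wobble leaves a
#' vanishing footprint at the old position and an appearing one at the new
#' position; both localise the same physical event). Recall is the
#' fraction of true events with at least one matching detection; precision
#' the fraction of detections matching at least one true event.
#'
#' @param detected data.frame from [detect_events()].
#' @param truth_events `truth$events` from [simulate_gliding_movie()].
#' @param match_radius_px centroid match radius (default 5).
#' @param match_frames frame tolerance (default 1).
#' @return list: n_true, n_detected, n_true_matched, n_det_matched,
#'   recall, precision.
#' @export
match_events <- function(detected, truth_events, match_radius_px = 5,
                         match_frames = 1L) {
  nt <- nrow(truth_events); nd <- nrow(detected)
  if (nt == 0L || nd == 0L)
    return(list(n_true = nt, n_detected = nd, n_true_matched = 0L,
                n_det_matched = 0L,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  hit <- matrix(FALSE, nt, nd)
  for (i in seq_len(nt)) {
    d1 <- sqrt((detected$row_px - truth_events$row_px[i])^2 +
               (detected$col_px - truth_events$col_px[i])^2)
    d2 <- sqrt((detected$row_px - truth_events$row_new[i])^2 +
               (detected$col_px - truth_events$col_new[i])^2)
    d2[is.na(d2)] <- Inf
    fok <- abs(detected$frame + 1L - truth_events$frame[i]) <= match_frames
    hit[i, ] <- fok & (d1 <= match_radius_px | d2 <= match_radius_px)
  }
  list(n_true = nt, n_detected = nd,
       n_true_matched = sum(apply(hit, 1L, any)),
       n_det_matched = sum(apply(hit, 2L, any)),
       recall = mean(apply(hit, 1L, any)),
       precision = mean(apply(hit, 2L, any)))
}

#' Recall/precision benchmark of the event detector
#'
#' Simulates `n_movies` gliding movies with event rates set so each movie
#' carries about `events_per_movie` true wobble/detach events, runs the
#' full pipeline (background statistics, threshold, ratio stack, spot
#' detection) on each, and pools matches over all movies. Detection runs
#' two-sided: simulated detachments are pure disappearances and carry no
#' brightening footprint, so the one-sided default cannot see them by
#' construction.
#'
#' @param n_movies number of independently seeded movies.
#' @param events_per_movie target expected true events per movie.
#' @param seed base seed; movie m uses seed + m.
#' @param config a [gliding_sim_config()] used as the base (its seed and
#'   event rates are overridden); NULL for defaults.
#' @param event_pars [event_params()] for detection; NULL for defaults
#'   with `two_sided = TRUE`.
#' @param match_radius_px,match_frames see [match_events()].
#' @return list: recall, precision, n_true, n_detected, per_movie
#'   (data.frame of per-movie counts).
#' @export
benchmark_event_detector <- function(n_movies = 20L, events_per_movie = 30,
                                     seed = 1L, config = NULL,
                                     event_pars = NULL,
                                     match_radius_px = 5,
                                     match_frames = 1L) {
  if (is.null(config)) config <- gliding_sim_config()
  if (is.null(event_pars)) event_pars <- event_params(two_sided = TRUE)
  # rates giving ~events_per_movie in expectation: detachment kept rare
  # (it depletes the field), the rest supplied by wobbles over the
  # expected alive-time under that detach rate
  dur <- (config$n_frames - 1L) * config$frame_interval_s
  r_det <- 0.008
  alive <- (1 - exp(-r_det * dur)) / r_det
  n_det_exp <- config$n_filaments * (1 - exp(-r_det * dur))
  r_wob <- max(0, (events_per_movie - n_det_exp) /
                 (config$n_filaments * alive))
  per <- vector("list", n_movies)
  tot <- c(nt = 0L, nd = 0L, ntm = 0L, ndm = 0L)
  for (m in seq_len(n_movies)) {
    cfg <- config
    cfg$seed <- as.integer(seed + m)
    cfg$wobble_rate_per_s <- r_wob
    cfg$detach_rate_per_s <- r_det
    sim <- simulate_gliding_movie(cfg)
    ed <- detect_movie_events(sim$movie, event_pars)
    mm <- match_events(ed$events, sim$truth$events, match_radius_px,
                       match_frames)
    per[[m]] <- data.frame(movie = m, n_true = mm$n_true,
                           n_detected = mm$n_detected,
                           n_true_matched = mm$n_true_matched,
                           n_det_matched = mm$n_det_matched)
    tot <- tot + c(mm$n_true, mm$n_detected, mm$n_true_matched,
                   mm$n_det_matched)
  }
  list(recall = tot[["ntm"]] / tot[["nt"]],
       precision = tot[["ndm"]] / tot[["nd"]],
       n_true = tot[["nt"]], n_detected = tot[["nd"]],
       per_movie = do.call(rbind, per))
}

#' False-positive rate of the detector on pure-background movies
#'
#' Simulates movies containing no filaments (background and noise only) at
#' the default configuration and counts detected events; under the default
#' threshold (k = 4) the expected count is essentially zero.
#'
#' @param n_movies number of movies (default 50).
#' @param seed base seed.
#' @param config base [gliding_sim_config()]; NULL for defaults.
#' @param event_pars [event_params()]; NULL for defaults with
#'   `two_sided = TRUE` (the stricter case: both tails can fire).
#' @return list: events_per_movie (mean), counts (per movie).
#' @export
background_false_positive_rate <- function(n_movies = 50L, seed = 1L,
                                           config = NULL,
                                           event_pars = NULL) {
  if (is.null(config)) config <- gliding_sim_config()
  if (is.null(event_pars)) event_pars <- event_params(two_sided = TRUE)
  counts <- integer(n_movies)
  for (m in seq_len(n_movies)) {
    cfg <- config
    cfg$n_filaments <- 0L
    cfg$seed <- as.integer(seed + m)
    sim <- simulate_gliding_movie(cfg)
    counts[m] <- nrow(detect_movie_events(sim$movie, event_pars)$events)
  }
  list(events_per_movie = mean(counts), counts = counts)
}
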