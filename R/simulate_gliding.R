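# Ground-truthed simulator of gliding-assay time-lapse movies.
#
# Filaments are smooth random curves stamped onto each frame as a line of
# constant linear intensity density, convolved with a Gaussian PSF, over an
# additive Gaussian background. Motile filaments translate rigidly along
# their mean tangent; wobble events displace a filament laterally within one
# frame; detach events remove it for all later frames.

#' Configuration for the gliding-assay movie simulator
#'
#' Defaults describe a 1-min movie at 1-s intervals (the nonmuscle-myosin
#' assay condition): a 256 x 256 field at 0.065 um/px with Gaussian
#' background (mean 100, SD 5) and filament peak amplitude 25 above
#' background (peak SNR 5). The PSF width (sigma 4 px) is deliberately at
#' the broad end of what surface-assay imaging produces, which places an
#' SNR-5 filament just above the ratio detector's detection floor; filament
#' lengths are truncated below at twice the PSF FWHM (shorter fragments are
#' unresolvable point spots, not assay filaments). See the methods vignette
#' for the reasoning behind both choices.
#'
#' @param n_filaments number of filaments seeded in the field.
#' @param length_mean_um,length_sd_um filament contour length distribution
#'   (normal, truncated positive), micrometres.
#' @param speed_um_per_s gliding speed of motile filaments.
#' @param motile_fraction probability a filament is motile (0-1).
#' @param wobble_rate_per_s,detach_rate_per_s per-filament Poisson rates of
#'   abrupt lateral displacement and of surface detachment.
#' @param wobble_jump_um lateral displacement of a wobble, micrometres.
#' @param min_separation_um minimum centre-to-centre distance between
#'   filaments at seeding (keeps the field sparse enough that objects are
#'   resolvable, as in a usable assay movie; gliding can still bring
#'   filaments together later).
#' @param psf_sigma_px Gaussian rendering width, pixels.
#' @param background_mean,background_sd additive background statistics.
#' @param filament_amplitude peak filament intensity above background.
#' @param image_shape integer c(rows, cols) of the field.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s seconds between frames.
#' @param n_frames number of frames.
#' @param seed RNG seed for reproducible simulation.
#' @return a validated list of class `gliding_sim_config`.
#' @export
gliding_sim_config <- function(n_filaments = 10L,
                               length_mean_um = 1.5, length_sd_um = 0.4,
                               speed_um_per_s = 0.2,
                               motile_fraction = 0.6,
                               wobble_rate_per_s = 0.02,
                               detach_rate_per_s = 0.01,
                               wobble_jump_um = 1.5,
                               min_separation_um = 3,
                               psf_sigma_px = 4,
                               background_mean = 100, background_sd = 5,
                               filament_amplitude = 25,
                               image_shape = c(256L, 256L),
                               pixel_size_um = 0.065,
                               frame_interval_s = 1,
                               n_frames = 60L,
                               seed = 1L) {
  cfg <- list(n_filaments = as.integer(n_filaments),
              length_mean_um = length_mean_um, length_sd_um = length_sd_um,
              speed_um_per_s = speed_um_per_s,
              motile_fraction = motile_fraction,
              wobble_rate_per_s = wobble_rate_per_s,
              detach_rate_per_s = detach_rate_per_s,
              wobble_jump_um = wobble_jump_um,
              min_separation_um = min_separation_um,
              psf_sigma_px = psf_sigma_px,
              background_mean = background_mean,
              background_sd = background_sd,
              filament_amplitude = filament_amplitude,
              image_shape = as.integer(image_shape),
              pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              n_frames = as.integer(n_frames),
              seed = as.integer(seed))
  with(cfg, {
    if (n_filaments < 0L) stop("n_filaments must be >= 0")
    if (length_mean_um <= 0 || length_sd_um < 0)
      stop("filament length distribution must have positive mean, SD >= 0")
    if (speed_um_per_s < 0) stop("speed_um_per_s must be >= 0")
    if (motile_fraction < 0 || motile_fraction > 1)
      stop("motile_fraction must lie in [0, 1]")
    if (wobble_rate_per_s < 0 || detach_rate_per_s < 0)
      stop("event rates must be >= 0")
    if (wobble_jump_um < 0) stop("wobble_jump_um must be >= 0")
    if (min_separation_um < 0) stop("min_separation_um must be >= 0")
    if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
    if (background_mean <= 0) stop("background_mean must be > 0")
    if (background_sd < 0) stop("background_sd must be >= 0")
    if (filament_amplitude < 0) stop("filament_amplitude must be >= 0")
    if (length(image_shape) != 2L || any(image_shape < 8L))
      stop("image_shape must be two dimensions of at least 8 px")
    if (pixel_size_um <= 0 || frame_interval_s <= 0)
      stop("pixel_size_um and frame_interval_s must be > 0")
    if (n_frames < 2L) stop("n_frames must be >= 2")
    fov_um <- min(image_shape) * pixel_size_um
    if (n_filaments > 0L &&
        length_mean_um + 2 * length_sd_um > 0.9 * fov_um)
      stop("configured filament lengths exceed the field of view")
  })
  structure(cfg, class = "gliding_sim_config")
}

# Run expr with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth random open curve of target contour length L_px, returned as an
# n x 2 matrix of (row, col) positions sampled at ~0.5 px arc spacing.
random_filament_curve <- function(L_px, ds_px = 0.5) {
  K <- 5L
  t0 <- stats::runif(1, 0, 2 * pi)
  u <- c(sin(t0), cos(t0))      # along-axis unit (row, col)
  p <- c(cos(t0), -sin(t0))     # perpendicular unit
  s <- seq(0, 1, length.out = K)
  jit <- stats::rnorm(K, 0, 0.03 * L_px)
  ctrl <- cbind(s * L_px * u[1] + jit * p[1],
                s * L_px * u[2] + jit * p[2])
  n <- max(4L, ceiling(L_px / ds_px))
  tt <- seq(0, 1, length.out = n)
  rows <- stats::spline(s, ctrl[, 1], xout = tt)$y
  cols <- stats::spline(s, ctrl[, 2], xout = tt)$y
  xy <- cbind(rows, cols)
  # rescale so the polyline length matches L_px
  seglen <- sqrt(rowSums(diff(xy)^2))
  tot <- sum(seglen)
  if (tot > 0) xy <- xy * (L_px / tot)
  xy
}

polyline_length <- function(xy) sum(sqrt(rowSums(diff(xy)^2)))

# Deposit curve samples (row, col) into an accumulator matrix as point
# masses of weight w each; samples outside the field are clipped.
stamp_points <- function(img, xy, w) {
  r <- round(xy[, 1]) + 1L
  c <- round(xy[, 2]) + 1L
  keep <- r >= 1L & r <= nrow(img) & c >= 1L & c <= ncol(img)
  if (!any(keep)) return(img)
  idx <- cbind(r[keep], c[keep])
  # accumulate duplicates
  key <- paste(idx[, 1], idx[, 2])
  tab <- tapply(rep(w, nrow(idx)), key, sum)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  img[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
    img[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] + as.numeric(tab)
  img
}

#' Simulate a gliding-assay movie with ground truth
#'
#' Generates filaments as smooth random curves, evolves them (gliding,
#' wobbling, detachment), and renders each frame by stamping the contour at
#' constant linear density, convolving with the Gaussian PSF, and adding
#' Gaussian background noise. The same config (including seed) always
#' produces a bit-identical movie and ground truth.
#'
#' @param config a [gliding_sim_config()].
#' @return a list with elements:
#'   \describe{
#'     \item{movie}{a [movie_stack()].}
#'     \item{truth}{a list: `filaments` (id, motile, speed_um_per_s,
#'       length_um), `tracks` (filament, frame, row_px, col_px — 0-based
#'       centroid of the live contour, plus offset_row/offset_col from the
#'       frame-0 position), `events` (filament, frame, type, row_px, col_px
#'       of the pre-event centroid and row_new/col_new of the post-event
#'       centroid, NA for detach), and `contours` (per-filament frame-0
#'       sample positions, px).}
#'   }
#' @export
simulate_gliding_movie <- function(config) {
  stopifnot(inherits(config, "gliding_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    H <- cfg$image_shape[1L]; W <- cfg$image_shape[2L]
    Tn <- cfg$n_frames
    dt <- cfg$frame_interval_s
    px <- cfg$pixel_size_um
    ds <- 0.5
    v_px <- cfg$speed_um_per_s * dt / px
    jump_px <- cfg$wobble_jump_um / px

    filaments <- list(); contours <- list()
    events <- list(); track_rows <- list()
    for (f in seq_len(cfg$n_filaments)) {
      # length distribution truncated below at twice the PSF FWHM: shorter
      # fragments are unresolvable point-like spots, not assay filaments
      fov_um <- min(H, W) * px
      lmin_um <- max(0.2, 2 * 2.3548 * cfg$psf_sigma_px * px)
      L_um <- -1
      while (L_um < lmin_um || L_um > 0.85 * fov_um)
        L_um <- stats::rnorm(1, cfg$length_mean_um, cfg$length_sd_um)
      L_px <- L_um / px
      xy <- random_filament_curve(L_px, ds)
      # place with margin so typical motion stays in the field, resampling
      # until the centre clears previously seeded filaments
      margin <- 3 * cfg$psf_sigma_px + 2
      sep_px <- cfg$min_separation_um / px
      prev_ctrs <- do.call(rbind, lapply(contours, colMeans))
      draw_ctr <- function()
        c(stats::runif(1, min(margin + L_px / 2, (H - 1) / 2),
                       max(H - 1 - margin - L_px / 2, (H - 1) / 2)),
          stats::runif(1, min(margin + L_px / 2, (W - 1) / 2),
                       max(W - 1 - margin - L_px / 2, (W - 1) / 2)))
      ctr <- draw_ctr()
      if (!is.null(prev_ctrs) && sep_px > 0) {
        tries <- 0L
        while (min(sqrt(rowSums(sweep(prev_ctrs, 2, ctr)^2))) < sep_px &&
               tries < 200L) {
          ctr <- draw_ctr()
          tries <- tries + 1L
        }
      }
      xy <- sweep(xy, 2, colMeans(xy)) # centre at origin
      xy <- sweep(xy, 2, ctr, "+")
      motile <- stats::runif(1) < cfg$motile_fraction
      axis <- xy[nrow(xy), ] - xy[1L, ]
      axis <- axis / sqrt(sum(axis^2))
      perp <- c(axis[2L], -axis[1L])

      # Poisson event schedules over the movie duration; a detach ends the
      # filament, so only the first detach and pre-detach wobbles are kept.
      dur <- (Tn - 1L) * dt
      wob_n <- stats::rpois(1, cfg$wobble_rate_per_s * dur)
      wob_t <- sort(stats::runif(wob_n, 0, dur))
      det_t <- if (cfg$detach_rate_per_s > 0)
        stats::rexp(1, cfg$detach_rate_per_s) else Inf
      wob_frames <- unique(pmin(pmax(ceiling(wob_t / dt), 1L), Tn - 1L))
      det_frame <- if (det_t <= dur) pmin(pmax(ceiling(det_t / dt), 1L),
                                          Tn - 1L) else NA_integer_
      if (!is.na(det_frame)) wob_frames <- wob_frames[wob_frames < det_frame]
      wob_sign <- sample(c(-1, 1), length(wob_frames), replace = TRUE)

      filaments[[f]] <- data.frame(
        filament = f, motile = motile,
        speed_um_per_s = if (motile) cfg$speed_um_per_s else 0,
        length_um = polyline_length(xy) * px,
        detach_frame = if (is.na(det_frame)) NA_integer_ else det_frame)
      contours[[f]] <- xy

      # keep filaments inside the field: gliding reflects off a soft
      # boundary, a wobble that would exit flips to the inward side
      bmar <- 3
      rext <- range(xy[, 1L]); cext <- range(xy[, 2L])
      inside <- function(o)
        rext[1L] + o[1L] >= bmar && rext[2L] + o[1L] <= H - 1 - bmar &&
        cext[1L] + o[2L] >= bmar && cext[2L] + o[2L] <= W - 1 - bmar

      off <- c(0, 0)
      for (t in 0:(Tn - 1L)) {
        alive <- is.na(det_frame) || t < det_frame
        prev_off <- off
        if (t > 0L && alive) {
          if (motile) {
            if (!inside(off + v_px * axis)) axis <- -axis
            off <- off + v_px * axis
          }
          wi <- which(wob_frames == t)
          if (length(wi) == 1L) {
            old_ctr <- ctr + prev_off
            if (!inside(off + wob_sign[wi] * jump_px * perp))
              wob_sign[wi] <- -wob_sign[wi]
            off <- off + wob_sign[wi] * jump_px * perp
            events[[length(events) + 1L]] <- data.frame(
              filament = f, frame = t, type = "wobble",
              row_px = old_ctr[1L], col_px = old_ctr[2L],
              row_new = (ctr + off)[1L], col_new = (ctr + off)[2L])
          }
        }
        if (!is.na(det_frame) && t == det_frame) {
          old_ctr <- ctr + prev_off
          events[[length(events) + 1L]] <- data.frame(
            filament = f, frame = t, type = "detach",
            row_px = old_ctr[1L], col_px = old_ctr[2L],
            row_new = NA_real_, col_new = NA_real_)
        }
        if (alive)
          track_rows[[length(track_rows) + 1L]] <- data.frame(
            filament = f, frame = t,
            row_px = ctr[1L] + off[1L], col_px = ctr[2L] + off[2L],
            offset_row = off[1L], offset_col = off[2L])
      }
    }

    truth <- list(
      filaments = if (length(filaments)) do.call(rbind, filaments) else
        data.frame(filament = integer(), motile = logical(),
                   speed_um_per_s = numeric(), length_um = numeric(),
                   detach_frame = integer()),
      tracks = if (length(track_rows)) do.call(rbind, track_rows) else
        data.frame(filament = integer(), frame = integer(),
                   row_px = numeric(), col_px = numeric(),
                   offset_row = numeric(), offset_col = numeric()),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(filament = integer(), frame = integer(),
                   type = character(), row_px = numeric(),
                   col_px = numeric(), row_new = numeric(),
                   col_new = numeric()),
      contours = contours)
    rownames(truth$tracks) <- NULL
    if (nrow(truth$events)) rownames(truth$events) <- NULL

    # line density so the rendered ridge peaks at filament_amplitude
    w <- cfg$filament_amplitude * cfg$psf_sigma_px * sqrt(2 * pi) * ds
    frames <- array(0, c(Tn, H, W))
    for (t in 0:(Tn - 1L)) {
      img <- matrix(0, H, W)
      live <- truth$tracks[truth$tracks$frame == t, , drop = FALSE]
      for (k in seq_len(nrow(live))) {
        f <- live$filament[k]
        xy <- sweep(contours[[f]], 2,
                    c(live$offset_row[k], live$offset_col[k]), "+")
        img <- stamp_points(img, xy, w)
      }
      if (max(img) > 0) img <- blur_frame(img, cfg$psf_sigma_px)
      img <- img + cfg$background_mean +
        matrix(stats::rnorm(H * W, 0, cfg$background_sd), H, W)
      frames[t + 1L, , ] <- pmax(img, 0)
    }
    list(movie = movie_stack(frames, px, cfg$frame_interval_s),
         truth = truth)
  })
}

#' Pixels truly covered by a filament's contour at a given frame
#'
#' Convenience oracle for segmentation tests: the set of pixels onto which
#' the filament's contour samples were stamped at frame `t`.
#'
#' @param truth ground truth from [simulate_gliding_movie()].
#' @param filament filament id.
#' @param t 0-based frame index.
#' @return integer matrix of 0-based (row, col) pixels, or NULL if the
#'   filament is not live at `t`.
#' @export
true_filament_pixels <- function(truth, filament, t) {
  tr <- truth$tracks
  row <- tr[tr$filament == filament & tr$frame == t, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  xy <- sweep(truth$contours[[filament]], 2,
              c(row$offset_row, row$offset_col), "+")
  unique(cbind(round(xy[, 1]), round(xy[, 2])))
}
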