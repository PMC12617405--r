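# Independent oracles and small fixture factories used across the suite.

# Brute-force dense 2-D Gaussian convolution with reflective padding:
# direct quadruple loop over the full 2-D kernel, sharing nothing with the
# package's separable implementation beyond the kernel definition.
dense_gaussian_blur <- function(frame, sigma) {
  r <- ceiling(4 * sigma)
  xs <- seq(-r, r)
  k2 <- outer(xs, xs, function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  k2 <- k2 / sum(k2)
  nr <- nrow(frame); nc <- ncol(frame)
  ri <- c((r + 1):2, seq_len(nr), (nr - 1):(nr - r))
  ci <- c((r + 1):2, seq_len(nc), (nc - 1):(nc - r))
  pad <- frame[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- sum(k2 * pad[i:(i + 2 * r), j:(j + 2 * r)])
    }
  }
  out
}

# A small, fast simulation config for tests that do not need the full
# default field: single filament in a compact field, two frames.
single_filament_config <- function(seed, n_frames = 2L, ...) {
  gliding_sim_config(seed = seed, n_filaments = 1L, motile_fraction = 0,
                     wobble_rate_per_s = 0, detach_rate_per_s = 0,
                     n_frames = n_frames, image_shape = c(128L, 128L), ...)
}

# Thin-mask imaging regime used for length-measurement tests: narrow PSF
# and bright filaments so the thresholded mask hugs the true contour.
thin_psf_config <- function(seed, ...) {
  gliding_sim_config(seed = seed, n_filaments = 1L, motile_fraction = 0,
                     wobble_rate_per_s = 0, detach_rate_per_s = 0,
                     n_frames = 2L, psf_sigma_px = 1.0,
                     filament_amplitude = 60, image_shape = c(128L, 128L),
                     length_mean_um = 2.5, length_sd_um = 0.8, ...)
}

thin_psf_seg_params <- function()
  segmentation_params(blur_sigma_px = 0.5, k_sigma = 4, min_area_px = 10)

# Movie made of two independently rendered static scenes: frames
# 0..(k-1) from scene A, k..(T-1) from scene B. Used to build exactly one
# appearance/disappearance event at a known frame.
splice_movies <- function(movie_a, movie_b, k) {
  fr <- movie_a$frames
  Tn <- dim(fr)[1L]
  fr[(k + 1L):Tn, , ] <- movie_b$frames[(k + 1L):Tn, , ]
  movie_stack(fr, movie_a$pixel_size_um, movie_a$frame_interval_s)
}

pure_background_movie <- function(seed, n_frames = 6L,
                                  shape = c(64L, 64L)) {
  cfg <- gliding_sim_config(seed = seed, n_filaments = 0L,
                            image_shape = shape, n_frames = n_frames)
  simulate_gliding_movie(cfg)$movie
}
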