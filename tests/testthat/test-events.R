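test_that("identical frames give a unit ratio stack and no events", {
  m <- movie_stack(array(100, c(4, 40, 40)), 0.1, 1)
  rs <- ratio_stack(m)
  expect_equal(range(rs$ratios), c(1, 1), tolerance = 1e-9)
  ev <- detect_events(rs, threshold = 1.2)
  expect_equal(nrow(ev), 0L)
  proj <- temporal_max_projection(rs)
  expect_equal(range(proj$projection), c(1, 1), tolerance = 1e-9)
  expect_true(all(proj$rgb == 0))   # everything at the clip floor
})

test_that("an appearing object produces a matching ratio peak", {
  # a plateau 4x background appears between the two frames
  f1 <- matrix(100, 48, 48)
  f2 <- f1
  f2[20:28, 20:28] <- 400
  m <- movie_stack(aperm(array(c(f1, f2), c(48, 48, 2)), c(3, 1, 2)),
                   0.1, 1)
  rs <- ratio_stack(m, event_params(epsilon = 0))
  expect_equal(max(rs$ratios), 4, tolerance = 0.05)
  pk <- arrayInd(which.max(rs$ratios[1, , ]), c(48, 48))
  expect_true(all(pk >= 20 & pk <= 29))
})

test_that("time reversal inverts the ratio stack", {
  sim <- simulate_gliding_movie(single_filament_config(71, n_frames = 4L))
  m <- sim$movie
  rev <- movie_stack(m$frames[4:1, , ], m$pixel_size_um,
                     m$frame_interval_s)
  p0 <- event_params(epsilon = 0)
  rs <- ratio_stack(m, p0)
  rr <- ratio_stack(rev, p0)
  for (i in 1:3)
    expect_equal(rr$ratios[i, , ], 1 / rs$ratios[4 - i, , ],
                 tolerance = 1e-9)
})

test_that("the background-derived threshold follows 1 + k * SD/mean", {
  expect_identical(event_threshold(100, 5, 4), 1.2)
  expect_identical(event_threshold(100, 0, 4), 1.0)
  expect_identical(event_threshold(50, 5, 4), 1.4)
  expect_error(event_threshold(0, 5, 4), "> 0")
  expect_error(event_threshold(100, -1, 4), ">= 0")
})

test_that("a single detachment is found once, where the filament was", {
  a <- simulate_gliding_movie(single_filament_config(72, n_frames = 12L))
  b <- pure_background_movie(73, n_frames = 12L, shape = c(128L, 128L))
  k <- 6L
  m <- splice_movies(a$movie, b, k)
  out <- detect_movie_events(m, event_params(two_sided = TRUE))
  expect_equal(nrow(out$events), 1L)
  expect_true(out$events$frame %in% c(k - 1L, k))
  ctr <- a$truth$tracks[a$truth$tracks$frame == k - 1L, ]
  d <- sqrt((out$events$row_px - ctr$row_px)^2 +
            (out$events$col_px - ctr$col_px)^2)
  expect_lt(d, 3)
})

test_that("a wobble lights up both the vacated and the landing site", {
  a <- simulate_gliding_movie(single_filament_config(74, n_frames = 8L))
  shifted <- a$movie
  shifted$frames <- a$movie$frames[, c(25:128, 1:24), ]  # move 24 px in rows
  b <- pure_background_movie(75, n_frames = 8L, shape = c(128L, 128L))
  sh2 <- b
  sh2$frames[5:8, , ] <- shifted$frames[5:8, , ]
  m <- splice_movies(a$movie, sh2, 4L)
  out <- detect_movie_events(m, event_params(two_sided = TRUE))
  ctr <- a$truth$tracks[a$truth$tracks$frame == 3L, ]
  old <- c(ctr$row_px, ctr$col_px)
  new <- c(ctr$row_px - 24, ctr$col_px)
  d_old <- min(sqrt((out$events$row_px - old[1])^2 +
                    (out$events$col_px - old[2])^2))
  d_new <- min(sqrt((out$events$row_px - new[1])^2 +
                    (out$events$col_px - new[2])^2))
  expect_lt(d_old, 5); expect_lt(d_new, 5)
  # the temporal max projection is supra-threshold at the landing site
  # (checked over a small window: any single pixel can dip with noise)
  rs <- ratio_stack(m)
  proj <- temporal_max_projection(rs)
  win <- proj$projection[round(new[1]) + 1L + (-3:3),
                         round(new[2]) + 1L + (-3:3)]
  expect_gt(max(win), out$threshold)
  expect_true(all(proj$projection >= apply(rs$ratios, c(2, 3), max) - 1e-12))
})

test_that("the event pipeline is invariant to intensity rescaling", {
  a <- simulate_gliding_movie(single_filament_config(76, n_frames = 10L))
  b <- pure_background_movie(77, n_frames = 10L, shape = c(128L, 128L))
  m <- splice_movies(a$movie, b, 5L)
  p <- event_params(epsilon = 0, two_sided = TRUE)
  e1 <- detect_movie_events(m, p)
  m2 <- movie_stack(m$frames * 3.7, m$pixel_size_um, m$frame_interval_s)
  e2 <- detect_movie_events(m2, p)
  expect_equal(e2$threshold, e1$threshold, tolerance = 1e-9)
  expect_equal(e2$events$frame, e1$events$frame)
  expect_equal(e2$events$row_px, e1$events$row_px, tolerance = 1e-6)
  expect_equal(e2$events$peak_ratio, e1$events$peak_ratio,
               tolerance = 1e-9)
})

test_that("raising the threshold multiplier never adds events", {
  cfg <- gliding_sim_config(seed = 78, wobble_rate_per_s = 0.04,
                            detach_rate_per_s = 0.01)
  sim <- simulate_gliding_movie(cfg)
  bg <- background_stats(sim$movie)
  counts <- vapply(c(3, 4, 5, 6), function(k) {
    p <- event_params(threshold_k = k, two_sided = TRUE)
    rs <- ratio_stack(sim$movie, p)
    thr <- event_threshold(bg$background_mean, bg$background_sd, k)
    nrow(detect_events(rs, thr, p))
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("wobble frequency per filament matches the generating rate", {
  # one-sided default: each wobble is counted once, at its landing site
  freqs <- c(); lambda <- 0.03 * 59
  for (s in 1:6) {
    cfg <- gliding_sim_config(seed = 900 + s, n_filaments = 10L,
                              motile_fraction = 0,
                              wobble_rate_per_s = 0.03,
                              detach_rate_per_s = 0)
    sim <- simulate_gliding_movie(cfg)
    sg <- segment_movie(sim$movie)
    trk <- link_tracks(sg$measures, 0.065, 1)
    out <- detect_movie_events(sim$movie)
    ef <- events_per_filament(out$events, trk, 0.065)
    freqs <- c(freqs, ef$frequency)
  }
  n_fil <- 6 * 10
  se <- sqrt(lambda / n_fil)
  expect_lt(abs(mean(freqs) - lambda), 3 * se)
})

test_that("events far from any track stay unassigned", {
  tracks <- data.frame(track_id = 1L, frame = 0:5, row_px = 10,
                       col_px = 10, length_um = 1)
  events <- data.frame(frame = 2L, row_px = c(11, 100),
                       col_px = c(10, 100), area_px = 10L,
                       peak_ratio = 1.5, n_merged = 1L,
                       type = "unclassified")
  ef <- events_per_filament(events, tracks, 0.1, max_disp_um = 2)
  expect_equal(ef$events$track_id, c(1L, NA_integer_))
  expect_equal(ef$n_unassigned, 1L)
  expect_equal(ef$frequency, 1)
  ef0 <- events_per_filament(events[0, ], tracks, 0.1)
  expect_equal(ef0$frequency, 0)
})
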