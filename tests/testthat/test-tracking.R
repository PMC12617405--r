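test_that("one persistent filament gives exactly one full-length track", {
  sim <- simulate_gliding_movie(single_filament_config(61, n_frames = 10L))
  sg <- segment_movie(sim$movie)
  trk <- link_tracks(sg$measures, 0.065, 1)
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_equal(nrow(trk), 10L)
})

test_that("distant filaments never swap identity", {
  cfg <- gliding_sim_config(seed = 62, n_filaments = 2L,
                            motile_fraction = 1, speed_um_per_s = 0.2,
                            wobble_rate_per_s = 0, detach_rate_per_s = 0,
                            n_frames = 10L, min_separation_um = 8)
  sim <- simulate_gliding_movie(cfg)
  sg <- segment_movie(sim$movie)
  trk <- link_tracks(sg$measures, 0.065, 1)
  expect_equal(length(unique(trk$track_id)), 2L)
  # every track stays near a single truth filament throughout
  for (id in unique(trk$track_id)) {
    p <- trk[trk$track_id == id, ]
    fils <- vapply(seq_len(nrow(p)), function(i) {
      tt <- sim$truth$tracks[sim$truth$tracks$frame == p$frame[i], ]
      tt$filament[which.min((tt$row_px - p$row_px[i])^2 +
                            (tt$col_px - p$col_px[i])^2)]
    }, integer(1L))
    expect_equal(length(unique(fils)), 1L)
  }
})

test_that("a detaching filament's track ends at the detachment", {
  # splice: filament present up to frame 5, background afterwards
  a <- simulate_gliding_movie(single_filament_config(63, n_frames = 10L))
  b <- pure_background_movie(64, n_frames = 10L, shape = c(128L, 128L))
  m <- splice_movies(a$movie, b, 5L)
  sg <- segment_movie(m)
  trk <- link_tracks(sg$measures, 0.065, 1)
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_lte(max(trk$frame), 5L)
})

test_that("track speed is exact on constructed tracks", {
  still <- data.frame(frame = 0:5, row_px = 10, col_px = 20)
  expect_equal(track_speed(still, 0.1, 1), 0)
  expect_false(classify_moving(still, 0.1, 1))

  straight <- data.frame(frame = 0:5, row_px = 10 + (0:5) * 4, col_px = 3)
  expect_equal(track_speed(straight, 0.1, 1), 0.4)
  expect_equal(track_net_displacement(straight, 0.1), 2.0)
  expect_true(classify_moving(straight, 0.1, 1))

  # a gap uses the true elapsed time
  gappy <- data.frame(frame = c(0, 1, 3), row_px = c(0, 4, 12), col_px = 0)
  expect_equal(track_speed(gappy, 0.1, 1), 0.4)
  expect_error(track_speed(straight[1, ], 0.1, 1), "fewer than 2")
})

test_that("sampling a circular path recovers speed up to the chord/arc factor", {
  R <- 50; v <- 0.5; px <- 0.1; dt <- 1
  omega <- v / (R * px)            # rad/s
  n_per_rev <- 2 * pi / (omega * dt)
  expect_gt(n_per_rev, 10)
  t <- 0:40
  circ <- data.frame(frame = t,
                     row_px = 60 + R * sin(omega * t * dt),
                     col_px = 60 + R * cos(omega * t * dt))
  chord_arc <- sin(omega * dt / 2) / (omega * dt / 2)
  sp <- track_speed(circ, px, dt)
  expect_equal(sp, v * chord_arc, tolerance = 1e-6)
  expect_lt(abs(sp - v) / v, 0.02)
})

test_that("gliding speed is recovered within 5% from rendered movies", {
  sps <- c()
  for (s in 1:20) {
    cfg <- gliding_sim_config(seed = 800 + s, n_filaments = 1L,
                              motile_fraction = 1, speed_um_per_s = 0.5,
                              wobble_rate_per_s = 0, detach_rate_per_s = 0,
                              n_frames = 12L)
    sim <- simulate_gliding_movie(cfg)
    sg <- segment_movie(sim$movie)
    trk <- link_tracks(sg$measures, 0.065, 1)
    ids <- unique(trk$track_id)
    if (length(ids) != 1L) next
    sps <- c(sps, track_speed(trk[trk$track_id == ids, ], 0.065, 1))
  }
  expect_gte(length(sps), 18)
  expect_lt(abs(mean(sps) - 0.5) / 0.5, 0.05)
})

test_that("the moving classification agrees with the simulator's motile flag", {
  got <- c(); want <- c()
  for (s in 1:25) {
    cfg <- gliding_sim_config(seed = 830 + s, n_filaments = 4L,
                              motile_fraction = 0.5,
                              wobble_rate_per_s = 0, detach_rate_per_s = 0,
                              n_frames = 15L, min_separation_um = 6)
    sim <- simulate_gliding_movie(cfg)
    sg <- segment_movie(sim$movie)
    trk <- link_tracks(sg$measures, 0.065, 1)
    for (id in unique(trk$track_id)) {
      p <- trk[trk$track_id == id, ]
      tt <- sim$truth$tracks[sim$truth$tracks$frame == p$frame[1], ]
      fil <- tt$filament[which.min((tt$row_px - p$row_px[1])^2 +
                                   (tt$col_px - p$col_px[1])^2)]
      got <- c(got, classify_moving(p, 0.065, 1))
      want <- c(want, sim$truth$filaments$motile[
        sim$truth$filaments$filament == fil])
    }
  }
  expect_gte(length(got), 90)
  expect_gte(mean(got == want), 0.95)
})

test_that("track identity is conserved on sparse fields", {
  n_tracks <- 0L; n_pure <- 0L
  for (s in 1:20) {
    cfg <- gliding_sim_config(seed = 860 + s, n_filaments = 5L,
                              motile_fraction = 0.4,
                              wobble_rate_per_s = 0, detach_rate_per_s = 0,
                              n_frames = 12L, min_separation_um = 6)
    sim <- simulate_gliding_movie(cfg)
    sg <- segment_movie(sim$movie)
    trk <- link_tracks(sg$measures, 0.065, 1)
    for (id in unique(trk$track_id)) {
      p <- trk[trk$track_id == id, ]
      fils <- vapply(seq_len(nrow(p)), function(i) {
        tt <- sim$truth$tracks[sim$truth$tracks$frame == p$frame[i], ]
        tt$filament[which.min((tt$row_px - p$row_px[i])^2 +
                              (tt$col_px - p$col_px[i])^2)]
      }, integer(1L))
      n_tracks <- n_tracks + 1L
      n_pure <- n_pure + (length(unique(fils)) == 1L)
    }
  }
  expect_gte(n_tracks, 80L)
  expect_gte(n_pure / n_tracks, 0.95)
})

test_that("motility summaries compute the documented ratios", {
  # 10 constructed tracks, 4 clearly moving
  mk <- function(id, step) data.frame(
    track_id = id, frame = 0:9,
    row_px = 10 * id + (0:9) * step, col_px = 5, length_um = 1)
  tracks <- do.call(rbind, c(lapply(1:4, mk, step = 4),
                             lapply(5:10, mk, step = 0)))
  measures <- data.frame(frame = rep(0:9, each = 10),
                         label = rep(1:10, 10),
                         row_px = 0, col_px = 0, area_px = 20,
                         length_um = 1)
  s <- summarize_motility(tracks, measures, 0.1, 1)
  expect_equal(s$percent_moving, 40)
  expect_equal(s$n_tracks, 10L)
  expect_equal(s$n_filaments, 10L)
  expect_equal(s$mean_speed_moving_um_per_s, 0.4)

  # permutation invariance
  perm <- tracks[sample(nrow(tracks)), ]
  expect_equal(summarize_motility(perm, measures, 0.1, 1), s)

  empty <- tracks[0, ]
  s0 <- summarize_motility(empty, measures, 0.1, 1)
  expect_equal(s0$n_tracks, 0L)
  expect_true(is.na(s0$percent_moving))
})

test_that("the observed moving fraction matches the configured motile fraction", {
  moving <- c()
  for (s in 1:10) {
    cfg <- gliding_sim_config(seed = 880 + s, n_filaments = 5L,
                              motile_fraction = 0.6,
                              wobble_rate_per_s = 0, detach_rate_per_s = 0,
                              n_frames = 12L, min_separation_um = 6)
    sim <- simulate_gliding_movie(cfg)
    sg <- segment_movie(sim$movie)
    trk <- link_tracks(sg$measures, 0.065, 1)
    for (id in unique(trk$track_id))
      moving <- c(moving, classify_moving(trk[trk$track_id == id, ],
                                          0.065, 1))
  }
  n <- length(moving)
  expect_gte(n, 45)
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(mean(moving) - 0.6), 3 * se)
})
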