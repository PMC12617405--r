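test_that("a filament-free simulation is pure background with the configured statistics", {
  cfg <- gliding_sim_config(seed = 21, n_filaments = 0L,
                            image_shape = c(96L, 96L), n_frames = 4L)
  sim <- simulate_gliding_movie(cfg)
  fr <- get_frame(sim$movie, 0)
  expect_equal(mean(fr), cfg$background_mean, tolerance = 0.01)
  expect_equal(sd(fr), cfg$background_sd, tolerance = 0.05)
  expect_equal(nrow(sim$truth$events), 0L)
  expect_equal(nrow(sim$truth$tracks), 0L)
})

test_that("with no motion or events all frames are identical up to noise", {
  cfg <- single_filament_config(22, n_frames = 5L)
  sim <- simulate_gliding_movie(cfg)
  expect_equal(nrow(sim$truth$events), 0L)
  # the noise-free signal is static: frame differences are zero-mean noise
  d <- sim$movie$frames[2, , ] - sim$movie$frames[1, , ]
  expect_lt(abs(mean(d)), 0.2)
  expect_equal(sd(d), sqrt(2) * cfg$background_sd, tolerance = 0.05)
  # and the truth track is stationary
  tr <- sim$truth$tracks
  expect_equal(length(unique(tr$row_px)), 1L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- gliding_sim_config(seed = 5, n_filaments = 4L, n_frames = 6L,
                            image_shape = c(128L, 128L))
  a <- simulate_gliding_movie(cfg)
  b <- simulate_gliding_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$tracks, b$truth$tracks)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_gliding_movie(single_filament_config(1)))
  expect_identical(runif(3), before)
})

test_that("rendered intensity is conserved under pure translation", {
  # noise-free movie, motile filament far from the boundary
  cfg <- gliding_sim_config(seed = 31, n_filaments = 1L,
                            motile_fraction = 1, speed_um_per_s = 0.2,
                            wobble_rate_per_s = 0, detach_rate_per_s = 0,
                            background_sd = 0, n_frames = 8L,
                            image_shape = c(160L, 160L))
  sim <- simulate_gliding_movie(cfg)
  bg <- cfg$background_mean * 160 * 160
  integ <- apply(sim$movie$frames, 1, sum) - bg
  expect_true(all(abs(integ / integ[1] - 1) < 0.01))
})

test_that("configured event rates produce Poisson-distributed ground-truth counts", {
  # 200 static filaments, wobble events only; chi-square GOF at alpha 0.01
  rate <- 0.03; dt <- 1; Tn <- 41L
  counts <- integer(0)
  for (s in 1:40) {
    cfg <- gliding_sim_config(seed = 600 + s, n_filaments = 5L,
                              motile_fraction = 0, detach_rate_per_s = 0,
                              wobble_rate_per_s = rate, n_frames = Tn,
                              image_shape = c(128L, 128L))
    sim <- simulate_gliding_movie(cfg)
    ev <- sim$truth$events
    counts <- c(counts, vapply(1:5, function(f)
      sum(ev$filament == f), integer(1L)))
  }
  expect_length(counts, 200L)
  lambda <- rate * (Tn - 1L) * dt
  brk <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(counts, brk))
  p <- c(dpois(0:2, lambda), 1 - ppois(2, lambda))
  gof <- chisq.test(as.vector(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("ground-truth events sit inside the movie and detaches are terminal", {
  cfg <- gliding_sim_config(seed = 8, wobble_rate_per_s = 0.05,
                            detach_rate_per_s = 0.02)
  sim <- simulate_gliding_movie(cfg)
  ev <- sim$truth$events
  expect_true(all(ev$frame >= 1 & ev$frame <= cfg$n_frames - 1))
  det <- ev[ev$type == "detach", ]
  for (i in seq_len(nrow(det))) {
    tr <- sim$truth$tracks[sim$truth$tracks$filament == det$filament[i], ]
    expect_lt(max(tr$frame), det$frame[i] + 1)
  }
})

test_that("oversized filaments relative to the field are rejected", {
  expect_error(gliding_sim_config(length_mean_um = 20,
                                  image_shape = c(64L, 64L)),
               "field of view")
})

test_that("simulated cell cohorts reproduce the requested distributions", {
  p <- cell_cohort_params$MEEE
  cells <- simulate_cells(1000, p$length_mean_um, p$length_sd_um,
                          p$width_mean_um, p$width_sd_um, seed = 7)
  se <- p$length_sd_um / sqrt(1000)
  expect_lt(abs(mean(cells$length_um) - p$length_mean_um), 3 * se)
  expect_true(all(cells$length_um > cells$width_um))
  expect_true(all(cells$width_um > 0))

  degenerate <- simulate_cells(5, 10, 0, 4, 0, seed = 1)
  expect_equal(unique(degenerate$length_um), 10)
  expect_equal(unique(degenerate$width_um), 4)

  again <- simulate_cells(1000, p$length_mean_um, p$length_sd_um,
                          p$width_mean_um, p$width_sd_um, seed = 7)
  expect_identical(cells, again)
  expect_error(simulate_cells(10, 10, -1, 4, 0.1), "SD")
})

test_that("ring traces follow the sampling grid and phase structure", {
  cfg <- ring_sim_config(coalescence_mean = 21, coalescence_sd = 0,
                         dwell_mean = 6, dwell_sd = 0,
                         constriction_mean = 45, constriction_sd = 0,
                         diameter_sd_um = 0, diameter_noise_um = 0,
                         n_cells = 1L, seed = 2)
  out <- simulate_ring_traces(cfg)
  tr <- out$traces
  expect_equal(nrow(tr), ceiling(72 / 3) + 1L)  # 0..72 min at 3-min steps
  expect_equal(out$truth$total_min, 72)
  ring <- tr[tr$state == "ring", ]
  constr <- ring$diameter_um[ring$time_min >= 27]
  expect_true(all(diff(constr) < 0))           # strictly decreasing
  expect_identical(tr$state[1], "nodes")
  expect_identical(tr$state[nrow(tr)], "done")
})

test_that("ring-trace cohorts recover the configured phase means", {
  cfg <- ring_sim_config(strain = "REE", n_cells = 25L, seed = 3)
  out <- simulate_ring_traces(cfg)
  p <- ring_phase_params$REE
  se <- p$coalescence_sd / sqrt(25)
  expect_lt(abs(mean(out$truth$coalescence_min) - p$coalescence_mean),
            3 * se)
  expect_identical(out$truth,
                   simulate_ring_traces(cfg)$truth)
})
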