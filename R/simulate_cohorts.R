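# Simulators for the cell-scale cohorts: septated-cell dimensions and
# cytokinetic-ring traces. Defaults reproduce the measured per-strain
# statistics of the MEEE (wild-type N-terminal sequence) and REE
# (arginylated) fission-yeast strains.

#' Per-strain cell-dimension statistics (mean, SD in micrometres)
#'
#' Length/width cohort parameters for septated cells of the MEEE and REE
#' strains, as measured in the source cohorts (n = 143 and 122 cells).
#' @format list of per-strain lists with length_mean_um, length_sd_um,
#'   width_mean_um, width_sd_um, n.
#' @export
cell_cohort_params <- list(
  MEEE = list(length_mean_um = 13.54, length_sd_um = 0.98,
              width_mean_um = 4.10, width_sd_um = 0.27, n = 143L),
  REE  = list(length_mean_um = 11.76, length_sd_um = 0.90,
              width_mean_um = 4.24, width_sd_um = 0.31, n = 122L))

#' Simulate a cohort of septated-cell dimensions
#'
#' Independent normal draws of length and width, resampled until
#' length > width > 0 (the spherocylinder constraint: total length includes
#' the hemispherical caps). SD = 0 is allowed and yields a degenerate
#' (identical-cell) cohort.
#'
#' @param n number of cells (>= 1).
#' @param length_mean_um,length_sd_um length distribution, micrometres.
#' @param width_mean_um,width_sd_um width distribution, micrometres.
#' @param seed RNG seed.
#' @param strain optional strain label attached to every cell.
#' @return data.frame with cell_id, strain, length_um, width_um.
#' @examples
#' head(simulate_cells(5, 13.54, 0.98, 4.10, 0.27, seed = 1))
#' @export
simulate_cells <- function(n, length_mean_um, length_sd_um,
                           width_mean_um, width_sd_um, seed = 1L,
                           strain = NA_character_) {
  if (n < 1L) stop("n must be >= 1")
  if (length_mean_um <= 0 || width_mean_um <= 0)
    stop("means must be > 0")
  if (length_sd_um < 0 || width_sd_um < 0)
    stop("SDs must be >= 0 (0 gives a degenerate cohort)")
  if (length_sd_um == 0 && width_sd_um == 0 &&
      length_mean_um <= width_mean_um)
    stop("degenerate cohort violates length > width")
  with_seed(seed, {
    L <- numeric(n); Wd <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        li <- stats::rnorm(1, length_mean_um, length_sd_um)
        wi <- stats::rnorm(1, width_mean_um, width_sd_um)
        if (wi > 0 && li > wi) break
      }
      L[i] <- li; Wd[i] <- wi
    }
    data.frame(cell_id = seq_len(n), strain = strain,
               length_um = L, width_um = Wd)
  })
}

#' Per-strain cytokinesis phase statistics (minutes; rate um/min)
#'
#' Phase-duration means and SDs for the MEEE and REE strains (n = 25 cells
#' each): node coalescence, dwell, ring constriction, and the implied total
#' and constriction rate.
#' @format list of per-strain lists.
#' @export
ring_phase_params <- list(
  MEEE = list(coalescence_mean = 16.20, coalescence_sd = 2.12,
              dwell_mean = 8.88, dwell_sd = 2.52,
              constriction_mean = 34.32, constriction_sd = 6.66,
              total_mean = 59.40, total_sd = 7.94,
              rate_mean = 0.106, rate_sd = 0.019, n = 25L),
  REE  = list(coalescence_mean = 20.52, coalescence_sd = 2.69,
              dwell_mean = 5.64, dwell_sd = 2.64,
              constriction_mean = 45.48, constriction_sd = 12.27,
              total_mean = 71.64, total_sd = 13.54,
              rate_mean = 0.083, rate_sd = 0.021, n = 25L))

#' Configuration for the ring-trace simulator
#'
#' Phase durations are drawn independently per cell from normal
#' distributions truncated at more than one frame interval (a phase shorter
#' than the sampling step is unobservable). Defaults take the per-strain
#' statistics from [ring_phase_params]; the initial ring diameter defaults
#' to 3.7 +/- 0.2 um, consistent with the measured constriction rates
#' (initial diameter = rate x constriction time).
#'
#' @param strain "MEEE" or "REE" to use the measured phase statistics, or
#'   NULL to supply all parameters explicitly.
#' @param coalescence_mean,coalescence_sd,dwell_mean,dwell_sd,constriction_mean,constriction_sd
#'   phase-duration distributions, minutes.
#' @param diameter_mean_um,diameter_sd_um initial ring diameter.
#' @param diameter_noise_um SD of per-sample diameter measurement noise.
#' @param frame_interval_min sampling interval, minutes (default 3).
#' @param n_cells number of cells.
#' @param seed RNG seed.
#' @return a validated list of class `ring_sim_config`.
#' @export
ring_sim_config <- function(strain = NULL,
                            coalescence_mean = 16.20, coalescence_sd = 2.12,
                            dwell_mean = 8.88, dwell_sd = 2.52,
                            constriction_mean = 34.32, constriction_sd = 6.66,
                            diameter_mean_um = 3.7, diameter_sd_um = 0.2,
                            diameter_noise_um = 0.05,
                            frame_interval_min = 3,
                            n_cells = 25L, seed = 1L) {
  if (!is.null(strain)) {
    p <- ring_phase_params[[match.arg(strain, names(ring_phase_params))]]
    coalescence_mean <- p$coalescence_mean; coalescence_sd <- p$coalescence_sd
    dwell_mean <- p$dwell_mean; dwell_sd <- p$dwell_sd
    constriction_mean <- p$constriction_mean
    constriction_sd <- p$constriction_sd
  }
  cfg <- list(strain = if (is.null(strain)) NA_character_ else strain,
              coalescence_mean = coalescence_mean,
              coalescence_sd = coalescence_sd,
              dwell_mean = dwell_mean, dwell_sd = dwell_sd,
              constriction_mean = constriction_mean,
              constriction_sd = constriction_sd,
              diameter_mean_um = diameter_mean_um,
              diameter_sd_um = diameter_sd_um,
              diameter_noise_um = diameter_noise_um,
              frame_interval_min = frame_interval_min,
              n_cells = as.integer(n_cells), seed = as.integer(seed))
  with(cfg, {
    if (any(c(coalescence_mean, dwell_mean, constriction_mean,
              diameter_mean_um) <= 0))
      stop("phase-duration and diameter means must be > 0")
    if (any(c(coalescence_sd, dwell_sd, constriction_sd, diameter_sd_um,
              diameter_noise_um) < 0))
      stop("SDs must be >= 0")
    if (frame_interval_min <= 0) stop("frame_interval_min must be > 0")
    if (n_cells < 1L) stop("n_cells must be >= 1")
  })
  structure(cfg, class = "ring_sim_config")
}

rnorm_trunc_above <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}

#' Simulate cytokinetic-ring traces with ground-truth phase durations
#'
#' For each cell, the three phase durations (coalescence, dwell,
#' constriction) and the initial diameter are drawn; the trace is sampled on
#' the regular frame grid: state `nodes` during coalescence, `ring` at the
#' initial diameter during dwell, then linearly decreasing diameter to zero
#' during constriction, then `done`. Small Gaussian measurement noise is
#' added to reported diameters.
#'
#' @param config a [ring_sim_config()].
#' @return list with `traces` (long data.frame: cell_id, strain, time_min,
#'   state, diameter_um) and `truth` (per-cell exact generating durations:
#'   cell_id, strain, coalescence_min, dwell_min, constriction_min,
#'   total_min, initial_diameter_um, rate_um_per_min).
#' @export
simulate_ring_traces <- function(config) {
  stopifnot(inherits(config, "ring_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    dt <- cfg$frame_interval_min
    traces <- list(); truth <- list()
    for (i in seq_len(cfg$n_cells)) {
      C <- rnorm_trunc_above(cfg$coalescence_mean, cfg$coalescence_sd, dt)
      D <- rnorm_trunc_above(cfg$dwell_mean, cfg$dwell_sd, dt)
      K <- rnorm_trunc_above(cfg$constriction_mean, cfg$constriction_sd, dt)
      d0 <- rnorm_trunc_above(cfg$diameter_mean_um, cfg$diameter_sd_um, 0.5)
      total <- C + D + K
      tt <- seq(0, by = dt, length.out = ceiling(total / dt) + 1L)
      state <- ifelse(tt < C, "nodes", ifelse(tt < total, "ring", "done"))
      dia <- rep(NA_real_, length(tt))
      ring <- state == "ring"
      dia[ring] <- ifelse(tt[ring] < C + D, d0,
                          d0 * (1 - (tt[ring] - (C + D)) / K))
      if (cfg$diameter_noise_um > 0)
        dia[ring] <- pmax(dia[ring] +
          stats::rnorm(sum(ring), 0, cfg$diameter_noise_um), 0.01)
      traces[[i]] <- data.frame(cell_id = i, strain = cfg$strain,
                                time_min = tt, state = state,
                                diameter_um = dia)
      truth[[i]] <- data.frame(cell_id = i, strain = cfg$strain,
                               coalescence_min = C, dwell_min = D,
                               constriction_min = K, total_min = total,
                               initial_diameter_um = d0,
                               rate_um_per_min = d0 / K)
    }
    list(traces = do.call(rbind, traces), truth = do.call(rbind, truth))
  })
}
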