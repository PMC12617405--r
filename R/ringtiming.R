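# Cytokinetic-ring phase timing.
#
# A per-cell trace samples ring state at regular intervals: `nodes` while
# cortical nodes coalesce into a ring, `ring` (with a diameter) while the
# assembled ring dwells and then constricts, `done` after constriction
# completes. The module segments a trace into the three phases with
# reproducible changepoint rules and summarises per strain.

#' Phase-timing parameters
#'
#' @param dwell_tolerance_frac a (median-smoothed) diameter within this
#'   fraction of the initial diameter still counts as dwelling
#'   (default 0.05).
#' @param smoothing_window odd number of ring samples for the running
#'   median that smooths the diameter series, and the number of initial
#'   ring samples whose median defines the initial diameter (default 3).
#' @param end_diameter_um constriction is considered complete below this
#'   diameter when the trace carries no explicit `done` state
#'   (default 0.5).
#' @return validated list of class `phase_params`.
#' @export
phase_params <- function(dwell_tolerance_frac = 0.05,
                         smoothing_window = 3L,
                         end_diameter_um = 0.5) {
  if (dwell_tolerance_frac <= 0 || dwell_tolerance_frac >= 1)
    stop("dwell_tolerance_frac must lie in (0, 1)")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd and >= 1")
  if (end_diameter_um <= 0) stop("end_diameter_um must be > 0")
  structure(list(dwell_tolerance_frac = dwell_tolerance_frac,
                 smoothing_window = smoothing_window,
                 end_diameter_um = end_diameter_um),
            class = "phase_params")
}

running_median <- function(x, w) {
  if (w <= 1L || length(x) < 3L) return(x)
  stats::runmed(x, k = min(w, length(x) - (length(x) %% 2L == 0L)),
                endrule = "median")
}

#' Segment one ring trace into phase durations
#'
#' Rules (all on the sampling grid, no subframe interpolation):
#' coalescence runs from the first `nodes` sample to the first `ring`
#' sample; the initial diameter is the median of the first
#' `smoothing_window` ring diameters; constriction onset is the sample
#' preceding the first ring sample whose smoothed diameter has dropped
#' below (1 - dwell_tolerance_frac) x initial and stays down; dwell runs
#' from ring start to onset; constriction runs from onset to the first
#' `done` sample, or — for traces without `done` — to the first sample
#' below `end_diameter_um`. Total time is the exact sum of the three
#' phases, and the constriction rate is initial diameter / constriction
#' time.
#'
#' @param trace data.frame for one cell: time_min (regular grid), state
#'   ("nodes"/"ring"/"done"), diameter_um (present where state == "ring").
#' @param params [phase_params()].
#' @return one-row data.frame: coalescence_min, dwell_min,
#'   constriction_min, total_min, initial_diameter_um, rate_um_per_min,
#'   censored (TRUE when constriction never completes; durations are then
#'   NA and the cell is excluded from summaries).
#' @export
segment_phases <- function(trace, params = phase_params()) {
  stopifnot(inherits(params, "phase_params"))
  need <- c("time_min", "state", "diameter_um")
  if (!all(need %in% names(trace)))
    stop("trace must have columns: ", paste(need, collapse = ", "))
  trace <- trace[order(trace$time_min), , drop = FALSE]
  st <- trace$state
  if (!any(st == "nodes") || !any(st == "ring"))
    stop("malformed trace: needs both `nodes` and `ring` states")
  first_nodes <- which(st == "nodes")[1L]
  first_ring <- which(st == "ring")[1L]
  if (first_ring < first_nodes)
    stop("malformed trace: `ring` precedes `nodes`")
  ring_idx <- which(st == "ring")
  dia <- trace$diameter_um[ring_idx]
  if (sum(is.finite(dia)) < 2L)
    stop("malformed trace: needs >= 2 ring diameter samples")
  tt <- trace$time_min

  coalescence <- tt[first_ring] - tt[first_nodes]
  w <- params$smoothing_window
  d0 <- stats::median(dia[seq_len(min(w, length(dia)))])
  sm <- running_median(dia, w)

  below <- sm < (1 - params$dwell_tolerance_frac) * d0
  onset_rel <- NA_integer_
  for (i in which(below)) {
    # require the drop to persist: no later smoothed sample back at full
    if (all(sm[i:length(sm)] < (1 - params$dwell_tolerance_frac) * d0 +
            1e-9)) { onset_rel <- i; break }
  }
  done_idx <- which(st == "done")
  if (is.na(onset_rel)) {
    # diameter never drops: censored unless the trace ends in `done`
    if (length(done_idx)) onset_rel <- length(dia)
    else return(censored_row(coalescence, d0))
  }
  onset_idx <- ring_idx[max(onset_rel - 1L, 1L)]  # last at-full sample
  dwell <- tt[onset_idx] - tt[first_ring]

  if (length(done_idx)) {
    end_idx <- done_idx[1L]
  } else {
    past <- ring_idx[which(sm < params$end_diameter_um)]
    past <- past[past >= onset_idx]
    if (length(past) == 0L) return(censored_row(coalescence, d0))
    end_idx <- past[1L]
  }
  constriction <- tt[end_idx] - tt[onset_idx]
  if (constriction <= 0) return(censored_row(coalescence, d0))
  data.frame(coalescence_min = coalescence, dwell_min = dwell,
             constriction_min = constriction,
             total_min = coalescence + dwell + constriction,
             initial_diameter_um = d0,
             rate_um_per_min = d0 / constriction,
             censored = FALSE)
}

censored_row <- function(coalescence, d0) {
  data.frame(coalescence_min = NA_real_, dwell_min = NA_real_,
             constriction_min = NA_real_, total_min = NA_real_,
             initial_diameter_um = d0, rate_um_per_min = NA_real_,
             censored = TRUE)
}

#' Segment every cell of a long trace table
#'
#' @param traces long data.frame (cell_id, strain, time_min, state,
#'   diameter_um), e.g. from [simulate_ring_traces()].
#' @param params [phase_params()].
#' @return data.frame with one row per cell (cell_id, strain + the
#'   [segment_phases()] fields).
#' @export
segment_all_phases <- function(traces, params = phase_params()) {
  ids <- unique(traces$cell_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- traces[traces$cell_id == id, , drop = FALSE]
    cbind(data.frame(cell_id = id, strain = tr$strain[1L]),
          segment_phases(tr, params))
  }))
}

#' Per-strain phase-timing summary with two-sample tests
#'
#' Censored cells are excluded. For each quantity (the three phases, the
#' total, and the constriction rate), per-strain mean/SD plus Wilcoxon
#' rank-sum and Welch t-test p-values between each strain pair.
#'
#' @param durations data.frame from [segment_all_phases()] (needs strain
#'   labels); each strain must retain >= 3 uncensored cells.
#' @return list: `summary`, `tests` (NULL with a single strain).
#' @export
summarize_phases <- function(durations) {
  d <- durations[!durations$censored, , drop = FALSE]
  strains <- unique(d$strain)
  if (length(strains) == 0L || any(table(d$strain) < 3L))
    stop("every strain needs at least 3 uncensored cells")
  qs <- c("coalescence_min", "dwell_min", "constriction_min", "total_min",
          "rate_um_per_min")
  summary <- do.call(rbind, lapply(strains, function(s) {
    g <- d[d$strain == s, , drop = FALSE]
    row <- data.frame(strain = s, n = nrow(g))
    for (q in qs) {
      row[[paste0(q, "_mean")]] <- mean(g[[q]])
      row[[paste0(q, "_sd")]] <- stats::sd(g[[q]])
    }
    row
  }))
  rownames(summary) <- NULL
  if (length(strains) < 2L) return(list(summary = summary, tests = NULL))
  pairs <- utils::combn(strains, 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- d[d$strain == pr[1L], , drop = FALSE]
    b <- d[d$strain == pr[2L], , drop = FALSE]
    do.call(rbind, lapply(qs, function(q) {
      data.frame(strain_a = pr[1L], strain_b = pr[2L], quantity = q,
                 p_wilcox = stats::wilcox.test(a[[q]], b[[q]],
                                               exact = FALSE)$p.value,
                 p_t = stats::t.test(a[[q]], b[[q]])$p.value)
    }))
  }))
  rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}
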