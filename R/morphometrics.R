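# Spherocylinder morphometrics of rod-shaped (fission-yeast) cells.
#
# A cell is modelled as a cylinder capped by two hemispheres; the measured
# length is the total length including the caps, the width is the cylinder
# diameter. At length == width the formulas reduce exactly to a sphere.

#' Spherocylinder volume
#'
#' V = pi (w/2)^2 (L - w) + (4/3) pi (w/2)^3, micrometres cubed.
#'
#' @param length_um total cell length including the hemispherical caps.
#' @param width_um cell width (cylinder diameter). Requires
#'   length_um >= width_um > 0. Vectorised.
#' @return volume in um^3.
#' @examples
#' cell_volume(13.54, 4.10)
#' cell_volume(2, 2)  # sphere: (4/3) * pi
#' @export
cell_volume <- function(length_um, width_um) {
  check_dims(length_um, width_um)
  r <- width_um / 2
  pi * r^2 * (length_um - width_um) + (4 / 3) * pi * r^3
}

#' Spherocylinder surface area
#'
#' SA = 2 pi (w/2) (L - w) + 4 pi (w/2)^2, micrometres squared.
#'
#' @inheritParams cell_volume
#' @return surface area in um^2.
#' @examples
#' cell_surface_area(13.54, 4.10)
#' @export
cell_surface_area <- function(length_um, width_um) {
  check_dims(length_um, width_um)
  r <- width_um / 2
  2 * pi * r * (length_um - width_um) + 4 * pi * r^2
}

check_dims <- function(length_um, width_um) {
  if (any(!is.finite(length_um)) || any(!is.finite(width_um)))
    stop("cell dimensions must be finite")
  if (any(width_um <= 0))
    stop("width_um must be > 0")
  if (any(length_um < width_um))
    stop("length_um must be >= width_um (total length includes the caps)")
  invisible(TRUE)
}

#' Per-cell morphometry records
#'
#' Computes volume and surface area for each cell; records violating
#' length >= width > 0 are dropped with a warning rather than failing the
#' cohort.
#'
#' @param cells data.frame with cell_id, strain, length_um, width_um.
#' @return data.frame with cell_id, strain, length_um, width_um,
#'   volume_um3, surface_area_um2.
#' @export
morphometry_records <- function(cells) {
  need <- c("cell_id", "strain", "length_um", "width_um")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  ok <- is.finite(cells$length_um) & is.finite(cells$width_um) &
    cells$width_um > 0 & cells$length_um >= cells$width_um
  if (any(!ok))
    warning(sprintf("dropping %d cell(s) violating length >= width > 0",
                    sum(!ok)))
  cells <- cells[ok, , drop = FALSE]
  cells$volume_um3 <- cell_volume(cells$length_um, cells$width_um)
  cells$surface_area_um2 <- cell_surface_area(cells$length_um,
                                              cells$width_um)
  cells
}

#' Per-strain morphometry summary with two-sample tests
#'
#' Per-cell volume/surface area are computed first, then averaged per
#' strain (the mean of a nonlinear formula over cells, not the formula at
#' the mean dimensions). Between each pair of strains, two-sided
#' Wilcoxon rank-sum p-values (normal approximation with tie correction)
#' are reported for length, width, volume and surface area.
#'
#' @param cells data.frame with cell_id, strain, length_um, width_um;
#'   at least 2 strains with >= 3 cells each.
#' @return list: `summary` (per strain: n and mean/SD of each parameter)
#'   and `tests` (strain pair, parameter, p_value).
#' @export
summarize_morphometry <- function(cells) {
  rec <- morphometry_records(cells)
  strains <- unique(rec$strain)
  counts <- table(rec$strain)
  if (length(strains) < 2L)
    stop("need at least 2 strains")
  if (any(counts < 3L))
    stop("every strain needs at least 3 cells")
  params <- c(length_um = "length_um", width_um = "width_um",
              volume_um3 = "volume_um3",
              surface_area_um2 = "surface_area_um2")
  summary <- do.call(rbind, lapply(strains, function(s) {
    g <- rec[rec$strain == s, , drop = FALSE]
    row <- data.frame(strain = s, n = nrow(g))
    for (p in names(params)) {
      row[[paste0(p, "_mean")]] <- mean(g[[p]])
      row[[paste0(p, "_sd")]] <- stats::sd(g[[p]])
    }
    row
  }))
  pairs <- utils::combn(strains, 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- rec[rec$strain == pr[1L], , drop = FALSE]
    b <- rec[rec$strain == pr[2L], , drop = FALSE]
    do.call(rbind, lapply(names(params), function(p) {
      pv <- suppressWarnings(
        stats::wilcox.test(a[[p]], b[[p]], exact = FALSE,
                           correct = TRUE)$p.value)
      if (is.na(pv)) pv <- 1  # zero-variance identical cohorts

      data.frame(strain_a = pr[1L], strain_b = pr[2L], parameter = p,
                 p_value = pv)
    }))
  }))
  rownames(summary) <- rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}
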