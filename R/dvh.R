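# Dose-volume histograms and metrics.
#
# The DVH is sample-based: the empirical distribution of per-voxel dose over
# the structure's occupied voxels. No pre-binning — binning (default 0.05 Gy)
# applies only to exported/plotted curves. Dx% is the exact supremum of
# {d : at least x% of the volume receives >= d} on the empirical
# distribution, i.e. the ceil(n*x/100)-th largest sample, so D100% is the
# minimum and V_rx >= 95% holds exactly after normalizing D95% to rx.

#' Compute a dose-volume histogram for one structure
#'
#' @param dose A `dose_grid` on the same grid as `mask` (resample first with
#'   [resample_dose()] if needed; no implicit resampling).
#' @param mask A non-empty `structure_mask`.
#' @return A `dvh_curve`: list with `structure_id`, `samples` (sorted
#'   ascending per-voxel doses in Gy), `volume_cc`, `voxel_cc`.
#' @export
compute_dvh <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!grid_equal(dose$grid, mask$grid)) {
    stop("dose and mask lie on different grids; resample the dose first", call. = FALSE)
  }
  if (!any(mask$occupancy)) {
    stop(sprintf("cannot compute DVH of empty structure '%s'", mask$structure_id),
         call. = FALSE)
  }
  structure(
    list(
      structure_id = mask$structure_id,
      samples = sort(dose$values[mask$occupancy]),
      volume_cc = volume_cc(mask),
      voxel_cc = voxel_volume_mm3(mask$grid) / 1000
    ),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %d voxels, %.2f cc, dose [%.2f, %.2f] Gy\n",
              x$structure_id, length(x$samples), x$volume_cc,
              min(x$samples), max(x$samples)))
  invisible(x)
}

# dose covering the hottest n_hot voxels (possibly fractional): the greatest
# dose d such that at least n_hot samples are >= d = the ceil(n_hot)-th
# largest sample.
dose_covering <- function(samples, n_hot) {
  n <- length(samples)
  k <- ceiling(n_hot - 1e-9)
  k <- max(1L, min(n, k))
  samples[n - k + 1]
}

#' Dose at volume (Dx% / Dcc)
#'
#' Greatest dose d such that at least x% of the structure volume (or v cm^3)
#' receives >= d, on the empirical voxel-dose distribution. D100% is the
#' minimum dose; D2% the near-maximum.
#'
#' @param dvh A `dvh_curve`.
#' @param percent Volume fraction in percent, in (0, 100]; exclusive with `cc`.
#' @param cc Absolute volume in cm^3, in (0, structure volume].
#' @return Dose in Gy.
#' @examples
#' # 100 voxels with doses 1..100 Gy: D95% = 6 Gy
#' @export
dose_at_volume <- function(dvh, percent = NULL, cc = NULL) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (is.null(percent) == is.null(cc)) {
    stop("supply exactly one of percent= or cc=", call. = FALSE)
  }
  n <- length(dvh$samples)
  if (!is.null(percent)) {
    stopifnot(percent > 0, percent <= 100)
    n_hot <- n * percent / 100
  } else {
    stopifnot(cc > 0)
    if (cc > dvh$volume_cc + 1e-9) {
      stop(sprintf("requested volume %.3f cc exceeds structure volume %.3f cc",
                   cc, dvh$volume_cc), call. = FALSE)
    }
    n_hot <- cc / dvh$voxel_cc
  }
  dose_covering(dvh$samples, n_hot)
}

#' Volume at dose (VxGy)
#'
#' Percentage of the structure volume receiving at least `gy` Gy. The
#' comparison carries a 1e-9 relative tolerance so that a voxel whose dose
#' equals the threshold up to floating-point rounding (e.g. the covering
#' voxel after prescription normalization) counts as covered.
#'
#' @param dvh A `dvh_curve`.
#' @param gy Dose threshold in Gy, >= 0.
#' @return Percent of volume in [0, 100].
#' @export
volume_at_dose <- function(dvh, gy) {
  stopifnot(inherits(dvh, "dvh_curve"), gy >= 0)
  100 * mean(dvh$samples >= gy - 1e-9 * max(1, gy))
}

#' Target homogeneity index
#'
#' `100 * (D5% - D95%) / rx`: the spread between the near-maximum and
#' near-minimum target dose as a percentage of the prescription. 0 for a
#' perfectly uniform dose; lower is more homogeneous.
#'
#' @param dvh A `dvh_curve` of the target.
#' @param rx Prescription dose in Gy, > 0.
#' @return HI in percent.
#' @export
homogeneity_index <- function(dvh, rx) {
  stopifnot(inherits(dvh, "dvh_curve"), rx > 0)
  100 * (dose_at_volume(dvh, percent = 5) - dose_at_volume(dvh, percent = 95)) / rx
}

#' Normalize a dose grid to the prescription
#'
#' Rescales the whole dose grid so that 95% of the target volume receives the
#' prescription dose: `scale = rx / D95%(target)`. After normalization
#' `D95%(target) == rx` to 1e-9 relative and `V_rx(target) >= 95` exactly on
#' the empirical distribution.
#'
#' @param dose A `dose_grid`.
#' @param target A non-empty `structure_mask` on the dose grid.
#' @param rx Prescription dose in Gy.
#' @param coverage_percent Covered volume fraction (default 95).
#' @return List with `dose` (scaled `dose_grid`) and `scale`.
#' @export
normalize_prescription <- function(dose, target, rx, coverage_percent = 95) {
  stopifnot(inherits(dose, "dose_grid"), rx > 0)
  dvh <- compute_dvh(dose, target)
  d95 <- dose_at_volume(dvh, percent = coverage_percent)
  if (d95 <= 0) {
    stop(sprintf("cannot normalize: D%g%% of '%s' is zero", coverage_percent,
                 target$structure_id), call. = FALSE)
  }
  scale <- rx / d95
  scaled <- dose_grid(dose$grid, dose$values * scale,
                      note = sprintf("%s; normalized x%.6g to D%g%%=%g Gy on %s",
                                     dose$note, scale, coverage_percent, rx,
                                     target$structure_id))
  list(dose = scaled, scale = scale)
}

#' Resample a dose grid onto another grid
#'
#' Trilinear interpolation of dose values at the target grid's voxel centers
#' (nearest-neighbor available by flag). Points outside the source grid get
#' 0 Gy.
#'
#' @param dose A `dose_grid`.
#' @param grid Target `spatial_grid`.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return A `dose_grid` on `grid`.
#' @export
resample_dose <- function(dose, grid, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(dose, "dose_grid"), inherits(grid, "spatial_grid"))
  if (grid_equal(dose$grid, grid)) return(dose_grid(grid, dose$values, dose$note))
  src <- dose$grid
  ctr <- grid_centers(grid)
  # fractional source indices (0-based)
  fx <- (ctr$x - src$origin[1]) / src$spacing[1]
  fy <- (ctr$y - src$origin[2]) / src$spacing[2]
  fz <- (ctr$z - src$origin[3]) / src$spacing[3]
  out <- numeric(nrow(ctr))
  if (method == "nearest") {
    ix <- round(fx); iy <- round(fy); iz <- round(fz)
    ok <- ix >= 0 & ix <= src$dims[1] - 1 & iy >= 0 & iy <= src$dims[2] - 1 &
      iz >= 0 & iz <= src$dims[3] - 1
    out[ok] <- dose$values[cbind(ix[ok] + 1, iy[ok] + 1, iz[ok] + 1)]
  } else {
    x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
    ok <- x0 >= 0 & x0 <= src$dims[1] - 2 & y0 >= 0 & y0 <= src$dims[2] - 2 &
      z0 >= 0 & z0 <= src$dims[3] - 2
    if (any(ok)) {
      wx <- fx[ok] - x0[ok]; wy <- fy[ok] - y0[ok]; wz <- fz[ok] - z0[ok]
      i <- x0[ok] + 1; j <- y0[ok] + 1; k <- z0[ok] + 1
      v <- dose$values
      out[ok] <-
        v[cbind(i,     j,     k)]     * (1 - wx) * (1 - wy) * (1 - wz) +
        v[cbind(i + 1, j,     k)]     * wx       * (1 - wy) * (1 - wz) +
        v[cbind(i,     j + 1, k)]     * (1 - wx) * wy       * (1 - wz) +
        v[cbind(i + 1, j + 1, k)]     * wx       * wy       * (1 - wz) +
        v[cbind(i,     j,     k + 1)] * (1 - wx) * (1 - wy) * wz +
        v[cbind(i + 1, j,     k + 1)] * wx       * (1 - wy) * wz +
        v[cbind(i,     j + 1, k + 1)] * (1 - wx) * wy       * wz +
        v[cbind(i + 1, j + 1, k + 1)] * wx       * wy       * wz
    }
  }
  dose_grid(grid, out, note = sprintf("%s; resampled (%s)", dose$note, method))
}

#' Tabulate a DVH curve for export or plotting
#'
#' Cumulative relative-volume curve evaluated on a regular dose axis.
#'
#' @param x A `dvh_curve`.
#' @param bin_gy Dose bin width for the exported axis (default 0.05 Gy).
#' @param ... Unused.
#' @return Tibble: `structure_id`, `dose_gy`, `volume_pct`, `volume_cc`.
#' @method tidy dvh_curve
#' @export
tidy.dvh_curve <- function(x, bin_gy = 0.05, ...) {
  dmax <- max(x$samples)
  axis <- seq(0, dmax + bin_gy, by = bin_gy)
  frac <- vapply(axis, function(d) mean(x$samples >= d), numeric(1))
  tibble::tibble(
    structure_id = x$structure_id,
    dose_gy = axis,
    volume_pct = 100 * frac,
    volume_cc = frac * x$volume_cc
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-line DVH summary
#'
#' @param x A `dvh_curve`.
#' @param ... Unused.
#' @return One-row tibble: `structure_id`, `volume_cc`, `min_gy`, `mean_gy`,
#'   `max_gy`, `d95_gy`, `d2_gy`.
#' @method glance dvh_curve
#' @export
glance.dvh_curve <- function(x, ...) {
  tibble::tibble(
    structure_id = x$structure_id,
    volume_cc = x$volume_cc,
    min_gy = min(x$samples),
    mean_gy = mean(x$samples),
    max_gy = max(x$samples),
    d95_gy = dose_at_volume(x, percent = 95),
    d2_gy = dose_at_volume(x, percent = 2)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' Plot one or more DVH curves
#'
#' @param object A `dvh_curve`.
#' @param ... Further `dvh_curve` objects to overlay.
#' @param bin_gy Dose axis bin width (default 0.05 Gy).
#' @return A ggplot object (cumulative volume % vs dose).
#' @method autoplot dvh_curve
#' @export
autoplot.dvh_curve <- function(object, ..., bin_gy = 0.05) {
  curves <- c(list(object), Filter(function(o) inherits(o, "dvh_curve"), list(...)))
  df <- purrr::map_dfr(curves, tidy, bin_gy = bin_gy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct,
                                   color = .data$structure_id)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", color = "Structure") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
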