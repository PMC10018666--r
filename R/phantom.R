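# Seeded synthetic HA-WBRT head phantom: CT, structure set and dose emulator.
#
# Geometry is deterministic (analytic ellipsoids and arc tubes voxelized on
# the grid); only the dose noise is stochastic, driven by the spec seed. The
# default parameters are frozen in inst/extdata/phantoms/default_head.yaml.

# voxels whose centers lie inside an ellipsoid
ellipsoid_occ <- function(grid, center, semiaxes) {
  ax <- axis_centers(grid)
  ex <- ((ax[[1]] - center[1]) / semiaxes[1])^2
  ey <- ((ax[[2]] - center[2]) / semiaxes[2])^2
  ez <- ((ax[[3]] - center[3]) / semiaxes[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) <= 1
}

# voxels within tube_radius of a circular arc at fixed x, arc in the y-z
# plane: (y, z) = (yc, zc) + R (cos phi, sin phi), phi in [phi0, phi1] deg
arc_tube_occ <- function(grid, x0, yc, zc, R, phi_deg, tube_radius) {
  ax <- axis_centers(grid)
  phis <- seq(phi_deg[1], phi_deg[2], length.out = max(16, ceiling(abs(diff(phi_deg)))))
  pts <- cbind(x0, yc + R * cos(phis * pi / 180), zc + R * sin(phis * pi / 180))
  # restrict to the tube's bounding box for speed
  inb <- function(axis_vals, lo, hi) which(axis_vals >= lo & axis_vals <= hi)
  ii <- inb(ax[[1]], min(pts[, 1]) - tube_radius, max(pts[, 1]) + tube_radius)
  jj <- inb(ax[[2]], min(pts[, 2]) - tube_radius, max(pts[, 2]) + tube_radius)
  kk <- inb(ax[[3]], min(pts[, 3]) - tube_radius, max(pts[, 3]) + tube_radius)
  occ <- array(FALSE, grid$dims)
  if (length(ii) == 0 || length(jj) == 0 || length(kk) == 0) return(occ)
  sub <- expand.grid(x = ax[[1]][ii], y = ax[[2]][jj], z = ax[[3]][kk])
  d2min <- rep(Inf, nrow(sub))
  for (p in seq_len(nrow(pts))) {
    d2 <- (sub$x - pts[p, 1])^2 + (sub$y - pts[p, 2])^2 + (sub$z - pts[p, 3])^2
    d2min <- pmin(d2min, d2)
  }
  occ[as.matrix(expand.grid(i = ii, j = jj, k = kk))] <- d2min <= tube_radius^2
  occ
}

# cylinder along y: axis at (x0, z0), y in [y0, y1]
cylinder_y_occ <- function(grid, x0, z0, y_range, radius) {
  ax <- axis_centers(grid)
  cx <- (ax[[1]] - x0)^2
  cz <- (ax[[3]] - z0)^2
  iny <- ax[[2]] >= y_range[1] & ax[[2]] <= y_range[2]
  rad <- outer(outer(cx, rep(1, grid$dims[2]), `*`), cz, `+`) # cx + cz broadcast
  occ <- rad <= radius^2
  occ & aperm(array(iny, dim = grid$dims[c(2, 1, 3)]), c(2, 1, 3))
}

#' Synthetic head-phantom specification
#'
#' Loads the frozen default parameters (grid, ellipsoid axes, hippocampal arc
#' geometry, nerve cylinders, nominal volumes) from the packaged YAML spec
#' and applies any overrides. All lengths are mm.
#'
#' @param ... Named overrides of the YAML fields (e.g. `seed = 7`, or nested
#'   lists such as `grid = list(dims = c(64, 64, 64))`).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(...) {
  spec <- yaml::read_yaml(rtplankit_example("phantoms", "default_head.yaml"))
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(spec[[nm]])) {
      spec[[nm]] <- utils::modifyList(spec[[nm]], overrides[[nm]])
    } else {
      spec[[nm]] <- overrides[[nm]]
    }
  }
  structure(spec, class = "phantom_spec")
}

#' Generate the synthetic HA-WBRT phantom
#'
#' Builds a CT image and the six planning structures of a
#' hippocampal-avoidance whole-brain case: `Body` (head ellipsoid), `PTV_3000`
#' (brain ellipsoid), `Hippocampi` (bilateral arc tubes, combined),
#' `OpticNerve_L`/`OpticNerve_R` (cylinders), `OpticChiasm` (small
#' ellipsoid). Geometry is deterministic; construction guarantees
#' `Hippocampi` strictly inside `PTV_3000` strictly inside `Body`, with optic
#' structures disjoint from the hippocampi.
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct` (list `grid`, `values` in HU), `masks` (named list
#'   of `structure_mask`), `grid`, and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spatial_grid(spec$grid$origin, spec$grid$spacing, spec$grid$dims)

  body_occ <- ellipsoid_occ(g, spec$body$center, spec$body$semiaxes)
  ptv_occ <- ellipsoid_occ(g, spec$brain$center, spec$brain$semiaxes)
  hip <- spec$hippocampi
  hip_l <- arc_tube_occ(g, -hip$x_offset, hip$arc_center_y, hip$arc_center_z,
                        hip$arc_radius, unlist(hip$phi_deg), hip$tube_radius)
  hip_r <- arc_tube_occ(g, hip$x_offset, hip$arc_center_y, hip$arc_center_z,
                        hip$arc_radius, unlist(hip$phi_deg), hip$tube_radius)
  nerve <- spec$optic_nerve
  on_l <- cylinder_y_occ(g, -nerve$x_offset, nerve$z, unlist(nerve$y_range), nerve$radius)
  on_r <- cylinder_y_occ(g, nerve$x_offset, nerve$z, unlist(nerve$y_range), nerve$radius)
  chi <- spec$optic_chiasm
  chiasm_occ <- ellipsoid_occ(g, chi$center, chi$semiaxes)

  masks <- list(
    Body = structure_mask(g, body_occ, "Body"),
    PTV_3000 = structure_mask(g, ptv_occ, "PTV_3000"),
    Hippocampi = structure_mask(g, hip_l | hip_r, "Hippocampi"),
    OpticNerve_L = structure_mask(g, on_l & body_occ, "OpticNerve_L"),
    OpticNerve_R = structure_mask(g, on_r & body_occ, "OpticNerve_R"),
    OpticChiasm = structure_mask(g, chiasm_occ & body_occ, "OpticChiasm")
  )

  if (!all(ptv_occ[masks$Hippocampi$occupancy])) {
    stop("phantom spec is geometrically impossible: hippocampi extend outside the brain PTV",
         call. = FALSE)
  }
  if (!all(body_occ[ptv_occ])) {
    stop("phantom spec is geometrically impossible: brain PTV extends outside the body",
         call. = FALSE)
  }
  optic <- masks$OpticNerve_L$occupancy | masks$OpticNerve_R$occupancy |
    masks$OpticChiasm$occupancy
  if (any(optic & masks$Hippocampi$occupancy)) {
    stop("phantom spec is geometrically impossible: optic structures overlap the hippocampi",
         call. = FALSE)
  }

  ct_vals <- array(spec$ct$air_hu, g$dims)
  ct_vals[body_occ] <- spec$ct$tissue_hu
  ct_vals[ptv_occ] <- spec$ct$brain_hu

  list(ct = list(grid = g, values = ct_vals), masks = masks, grid = g, spec = spec)
}

#' Dose-model specification for the synthetic phantom
#'
#' Loads the frozen dose-model defaults (prescription plateau with smooth
#' ripple, Gaussian cold wells on the hippocampi, exponential falloff outside
#' the PTV, seeded additive noise) from the packaged YAML and applies
#' overrides.
#'
#' @param ... Named overrides (e.g. `noise_sd_gy = 0`, `seed = 3`).
#' @return A `dose_model_spec` list.
#' @export
dose_model_spec <- function(...) {
  spec <- yaml::read_yaml(rtplankit_example("phantoms", "default_dose_model.yaml"))
  overrides <- list(...)
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  stopifnot(spec$cold_well_depth > 0, spec$cold_well_depth < 1,
            spec$falloff_length_mm > 0)
  structure(spec, class = "dose_model_spec")
}

#' Emulate an HA-WBRT dose distribution on the phantom
#'
#' Dose = prescription-level plateau with a smooth low-amplitude ripple
#' inside the PTV, minus a Gaussian cold well around the hippocampi (depth a
#' fraction of the prescription, width `cold_well_sigma_mm`), exponential
#' falloff with distance outside the PTV, plus seeded Gaussian noise, clipped
#' at 0 Gy. This emulates the shape of a planned HA-WBRT distribution (target
#' coverage with a carved hippocampal well); it is not a physical dose
#' calculation.
#'
#' @param structures Output of [generate_phantom()] (or a named mask list
#'   containing `PTV_3000` and `Hippocampi`).
#' @param model A [dose_model_spec()].
#' @return A `dose_grid`.
#' @export
generate_dose <- function(structures, model = dose_model_spec()) {
  stopifnot(inherits(model, "dose_model_spec"))
  masks <- if (!is.null(structures$masks)) structures$masks else structures
  ptv <- masks$PTV_3000
  hippo <- masks$Hippocampi
  stopifnot(inherits(ptv, "structure_mask"), inherits(hippo, "structure_mask"))
  g <- ptv$grid
  rx <- model$rx_gy

  ax <- axis_centers(g)
  ripple <- model$ripple_frac *
    outer(outer(sin(2 * pi * ax[[1]] / model$ripple_period_mm),
                sin(2 * pi * ax[[2]] / (model$ripple_period_mm * 1.17)), `*`),
          sin(2 * pi * ax[[3]] / (model$ripple_period_mm * 1.31)), `*`)

  base <- array(0, g$dims)
  base[ptv$occupancy] <- rx
  d_ptv <- distance_map_mm(ptv, max_mm = model$falloff_max_mm)
  outside <- !ptv$occupancy
  fall <- exp(-pmin(d_ptv[outside], model$falloff_max_mm) / model$falloff_length_mm)
  base[outside] <- rx * fall
  base <- base * (1 + ripple)

  d_hip <- distance_map_mm(hippo, max_mm = 6 * model$cold_well_sigma_mm)
  well <- rx * model$cold_well_depth *
    exp(-pmin(d_hip, 6 * model$cold_well_sigma_mm)^2 / (2 * model$cold_well_sigma_mm^2))

  vals <- base - well
  if (model$noise_sd_gy > 0) {
    set.seed(model$seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, model$noise_sd_gy), g$dims)
  }
  dose_grid(g, pmax(vals, 0),
            note = sprintf("synthetic HA-WBRT dose emulator (seed %d)", model$seed))
}
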