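# VMAT plan-skeleton layout: isocenter placement, field instantiation from
# the template, and jaw fitting to the target's beam's-eye-view projection.
#
# Angle conventions (IEC 61217): gantry 0 deg = beam entering from anterior,
# rotating towards the patient's left with increasing angle. In LPS patient
# coordinates the beam's-eye-view crossline axis at gantry g is
# u(g) = (cos g, sin g, 0); the in-plane axis is patient +z. A collimator
# rotation t rotates (u, v) about the beam axis.

#' Place the isocenter at the target center
#'
#' Center of the target's axis-aligned bounding box (of occupied voxel
#' centers), rounded to 0.1 mm. The bounding-box center is preferred over the
#' centroid for robustness against asymmetric inferior extent; the centroid
#' is available via [centroid()] for comparison.
#'
#' @param target A non-empty `structure_mask`.
#' @return Numeric length 3 (x, y, z) mm.
#' @export
place_isocenter <- function(target) {
  stopifnot(inherits(target, "structure_mask"))
  bb <- mask_bbox(target)
  if (is.null(bb)) {
    stop(sprintf("cannot place isocenter: structure '%s' is empty", target$structure_id),
         call. = FALSE)
  }
  round((bb$min + bb$max) / 2, 1)
}

#' Instantiate plan fields from a clinical protocol
#'
#' One planned field per template field, all sharing the isocenter. The
#' machine id comes from the template unless overridden; an override is
#' recorded as a tracked change in the returned layout.
#'
#' @param protocol A `clinical_protocol`.
#' @param isocenter Numeric length 3, mm.
#' @param machine_id Optional override of the template machine.
#' @param machine_registry Optional character vector of known machines; an
#'   unknown effective machine id is an error when supplied.
#' @param plan_id Plan label.
#' @return A `plan_layout`: list with `plan_id`, `machine_id`, `isocenter`,
#'   `fields` (tibble with jaw columns `x1`, `x2`, `y1`, `y2` initialized NA),
#'   `prescription`, and `changes` (tibble of tracked overrides).
#' @export
build_fields <- function(protocol, isocenter, machine_id = NULL,
                         machine_registry = NULL, plan_id = "auto_plan") {
  stopifnot(inherits(protocol, "clinical_protocol"), length(isocenter) == 3)
  changes <- new_change_log()
  effective_machine <- protocol$machine_id
  if (!is.null(machine_id) && !identical(machine_id, protocol$machine_id)) {
    changes <- track_parameter("machine", protocol$machine_id, machine_id, changes)
    effective_machine <- machine_id
  }
  if (!is.null(machine_registry) && !effective_machine %in% machine_registry) {
    stop(sprintf("unknown machine id '%s' (registry: %s)", effective_machine,
                 paste(machine_registry, collapse = ", ")), call. = FALSE)
  }
  fields <- dplyr::mutate(
    protocol$fields,
    x1 = NA_real_, x2 = NA_real_, y1 = NA_real_, y2 = NA_real_
  )
  structure(
    list(
      plan_id = plan_id,
      machine_id = effective_machine,
      isocenter = as.numeric(isocenter),
      fields = fields,
      prescription = protocol$prescription,
      changes = changes
    ),
    class = "plan_layout"
  )
}

#' @export
print.plan_layout <- function(x, ...) {
  cat(sprintf("<plan_layout> '%s' on %s: %d fields, isocenter (%.1f, %.1f, %.1f) mm\n",
              x$plan_id, x$machine_id, nrow(x$fields),
              x$isocenter[1], x$isocenter[2], x$isocenter[3]))
  invisible(x)
}

# gantry angles sampled along an arc (degrees), honoring travel direction;
# CW increases the IEC angle, CC decreases, both modulo 360.
arc_sample_angles <- function(gantry_start, gantry_stop, rotation, step_deg) {
  if (rotation == "NONE") return(gantry_start %% 360)
  span <- if (rotation == "CW") (gantry_stop - gantry_start) %% 360
          else (gantry_start - gantry_stop) %% 360
  if (span == 0) span <- 360
  offsets <- unique(c(seq(0, span, by = step_deg), span))
  if (rotation == "CW") (gantry_start + offsets) %% 360 else (gantry_start - offsets) %% 360
}

# BEV coordinates (crossline u, inplane v) of points relative to isocenter
bev_project <- function(pts, isocenter, gantry_deg, collimator_deg) {
  rel <- sweep(pts, 2, isocenter)
  gr <- gantry_deg * pi / 180
  u <- rel[, 1] * cos(gr) + rel[, 2] * sin(gr)
  v <- rel[, 3]
  cr <- collimator_deg * pi / 180
  cbind(u * cos(cr) + v * sin(cr), -u * sin(cr) + v * cos(cr))
}

#' Fit jaws to enclose the target over an arc
#'
#' Projects every occupied target voxel center into the beam's eye view
#' (orthographic, collimator rotation applied) at gantry angles sampled every
#' `step_deg` along the field's arc, and sets the jaws to the projected
#' extents plus `margin_mm` on all sides.
#'
#' @param target A non-empty `structure_mask`.
#' @param field One-row tibble from a `plan_layout` `fields` table.
#' @param isocenter Numeric length 3, mm.
#' @param margin_mm Margin added on all four sides (default 7).
#' @param step_deg Angular sampling step along the arc (default 10).
#' @return The field row with `x1`, `x2`, `y1`, `y2` filled (mm at the
#'   isocenter plane). Errors if any jaw would exceed the 200 mm half-field.
#' @export
fit_jaws <- function(target, field, isocenter, margin_mm = 7, step_deg = 10) {
  stopifnot(inherits(target, "structure_mask"), margin_mm >= 0)
  idx <- which(target$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop(sprintf("cannot fit jaws: structure '%s' is empty", target$structure_id),
         call. = FALSE)
  }
  g <- target$grid
  pts <- cbind(
    g$origin[1] + (idx[, 1] - 1) * g$spacing[1],
    g$origin[2] + (idx[, 2] - 1) * g$spacing[2],
    g$origin[3] + (idx[, 3] - 1) * g$spacing[3]
  )
  angles <- arc_sample_angles(field$gantry_start, field$gantry_stop,
                              field$rotation, step_deg)
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (a in angles) {
    uv <- bev_project(pts, isocenter, a, field$collimator)
    lo <- pmin(lo, c(min(uv[, 1]), min(uv[, 2])))
    hi <- pmax(hi, c(max(uv[, 1]), max(uv[, 2])))
  }
  x1 <- lo[1] - margin_mm; x2 <- hi[1] + margin_mm
  y1 <- lo[2] - margin_mm; y2 <- hi[2] + margin_mm
  if (max(abs(c(x1, x2, y1, y2))) > 200) {
    stop("target projection exceeds the 200 mm half-field limit", call. = FALSE)
  }
  field$x1 <- x1; field$x2 <- x2; field$y1 <- y1; field$y2 <- y2
  field
}

#' Fit jaws for every field of a plan layout
#'
#' @param layout A `plan_layout`.
#' @param target A non-empty `structure_mask`.
#' @param margin_mm,step_deg Passed to [fit_jaws()].
#' @return The layout with all jaw columns filled.
#' @export
fit_all_jaws <- function(layout, target, margin_mm = 7, step_deg = 10) {
  stopifnot(inherits(layout, "plan_layout"))
  layout$fields <- purrr::map_dfr(seq_len(nrow(layout$fields)), function(i) {
    fit_jaws(target, layout$fields[i, ], layout$isocenter, margin_mm, step_deg)
  })
  layout
}
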