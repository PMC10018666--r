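# Plain-text case interchange format.
#
# A case directory holds:
#   case.json        grid, image metadata (modality, acquisition date),
#                    structure-set id, referencing plans, structure index
#   structures.json  per-structure planar contours (closed polygons by slice)
#   ct.csv           CT values (HU), one per line in array (column-major) order
#   dose.csv         optional dose values (Gy), same order
#   rtplan.json      optional plan-layout skeleton
# Everything is human-readable text; contours round-trip through
# rasterize_contours()/mask_to_contours() within the half-voxel tolerance,
# dose values exactly.

grid_to_list <- function(grid) {
  list(origin = grid$origin, spacing = grid$spacing, dims = grid$dims)
}

grid_from_list <- function(x) spatial_grid(x$origin, x$spacing, x$dims)

contours_to_list <- function(cs) {
  list(
    structure_id = cs$structure_id,
    color = cs$color,
    slices = lapply(cs$slices, function(s) {
      list(z = s$z, polygons = lapply(s$polygons, function(p) unname(as.matrix(p))))
    })
  )
}

contours_from_list <- function(x) {
  slices <- lapply(x$slices, function(s) {
    list(z = as.numeric(s$z),
         polygons = lapply(s$polygons, function(p) {
           m <- if (is.matrix(p)) p else do.call(rbind, lapply(p, unlist))
           matrix(as.numeric(m), ncol = 2)
         }))
  })
  contour_set(x$structure_id, slices, color = as.integer(unlist(x$color)))
}

layout_to_list <- function(layout) {
  list(
    plan_id = layout$plan_id,
    machine_id = layout$machine_id,
    isocenter = layout$isocenter,
    prescription = layout$prescription,
    fields = layout$fields,
    changes = layout$changes
  )
}

#' Write a case to a plain-text directory
#'
#' @param directory Output directory (created if absent).
#' @param ct List with `grid` and `values` (HU array), e.g. from
#'   [generate_phantom()].
#' @param masks Named list of `structure_mask` objects (written as contours).
#' @param dose Optional `dose_grid`.
#' @param layout Optional `plan_layout`.
#' @param case_id Case label.
#' @param modality Image modality text (default `"CT"`).
#' @param acquisition_date Image acquisition date.
#' @param referencing_plans Plans already referencing the structure set.
#' @return `directory`, invisibly.
#' @export
write_case <- function(directory, ct, masks, dose = NULL, layout = NULL,
                       case_id = "case", modality = "CT",
                       acquisition_date = Sys.Date(),
                       referencing_plans = character()) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  grid <- ct$grid
  for (m in masks) {
    if (!grid_equal(grid, m$grid)) stop("mask grid differs from CT grid", call. = FALSE)
  }
  if (!is.null(dose) && !grid_equal(grid, dose$grid)) {
    stop("dose grid differs from CT grid", call. = FALSE)
  }
  header <- list(
    case_id = case_id,
    structure_set_id = paste0(case_id, "_SS"),
    modality = modality,
    acquisition_date = format(as.Date(acquisition_date)),
    referencing_plans = as.character(referencing_plans),
    grid = grid_to_list(grid),
    structures = lapply(unname(masks), function(m) {
      list(id = m$structure_id, volume_cc = volume_cc(m))
    })
  )
  tryCatch({
    jsonlite::write_json(header, file.path(directory, "case.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    contour_sets <- lapply(unname(masks), function(m) contours_to_list(mask_to_contours(m)))
    jsonlite::write_json(contour_sets, file.path(directory, "structures.json"),
                         auto_unbox = TRUE, digits = NA)
    write_numeric_lines(as.vector(ct$values), file.path(directory, "ct.csv"))
    if (!is.null(dose)) {
      write_numeric_lines(as.vector(dose$values), file.path(directory, "dose.csv"))
    }
    if (!is.null(layout)) {
      jsonlite::write_json(layout_to_list(layout), file.path(directory, "rtplan.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }, error = function(e) {
    stop(sprintf("failed writing case to '%s': %s", directory, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(directory)
}

# plain-text numeric vector I/O at full double precision
write_numeric_lines <- function(values, path) {
  writeLines(sprintf("%.17g", values), path)
}

read_values <- function(path, n_expected) {
  v <- as.numeric(readLines(path))
  if (length(v) != n_expected) {
    stop(sprintf("'%s' holds %d values, expected %d", path, length(v), n_expected),
         call. = FALSE)
  }
  v
}

#' Read a case directory
#'
#' Contours are re-rasterized onto the case grid to recover structure masks.
#'
#' @param directory A directory written by [write_case()].
#' @return List with `case_id`, `grid`, `ct`, `masks` (named list), `dose`
#'   (`dose_grid` or NULL), `contours` (named list of `contour_set`),
#'   `modality`, `acquisition_date`, `structure_set_id`, `referencing_plans`.
#' @export
read_case <- function(directory) {
  header_path <- file.path(directory, "case.json")
  if (!file.exists(header_path)) {
    stop(sprintf("no case.json under '%s'", directory), call. = FALSE)
  }
  header <- jsonlite::read_json(header_path, simplifyVector = FALSE)
  grid <- grid_from_list(lapply(header$grid, unlist))
  nvox <- prod(grid$dims)

  ct_vals <- array(read_values(file.path(directory, "ct.csv"), nvox), grid$dims)

  raw_contours <- jsonlite::read_json(file.path(directory, "structures.json"),
                                      simplifyVector = FALSE)
  contours <- lapply(raw_contours, contours_from_list)
  names(contours) <- vapply(contours, function(cs) cs$structure_id, character(1))
  masks <- lapply(contours, function(cs) {
    if (length(cs$slices) == 0) empty_mask(grid, cs$structure_id)
    else rasterize_contours(cs, grid)
  })

  dose_path <- file.path(directory, "dose.csv")
  dose <- if (file.exists(dose_path)) {
    dose_grid(grid, array(read_values(dose_path, nvox), grid$dims),
              note = sprintf("read from %s", dose_path))
  } else NULL

  list(
    case_id = header$case_id,
    structure_set_id = header$structure_set_id,
    modality = header$modality,
    acquisition_date = as.Date(header$acquisition_date),
    referencing_plans = as.character(unlist(header$referencing_plans)),
    grid = grid, ct = list(grid = grid, values = ct_vals),
    masks = masks, contours = contours, dose = dose
  )
}
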