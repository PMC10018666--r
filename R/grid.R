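#' Axis-aligned spatial grid in patient coordinates
#'
#' The geometric frame shared by every voxelized object in the package.
#' Coordinates follow the DICOM patient convention (LPS: x towards patient
#' left, y towards posterior, z towards superior), in millimetres. Voxels are
#' indexed from 0 and represented by their centers: voxel `(i, j, k)` has
#' center `origin + c(i, j, k) * spacing`. Only identity-orientation
#' (axis-aligned axial) grids are supported; oblique acquisitions must be
#' resampled upstream.
#'
#' @param origin Numeric length 3; patient-coordinate center of voxel (0,0,0),
#'   in mm.
#' @param spacing Numeric length 3; per-axis voxel size in mm, strictly
#'   positive.
#' @param dims Integer length 3; voxel counts per axis, each >= 1.
#' @return A `spatial_grid` object.
#' @examples
#' g <- spatial_grid(origin = c(-50, -50, -50), spacing = c(1, 1, 1),
#'                   dims = c(101, 101, 101))
#' @export
spatial_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3)
  if (any(!is.finite(origin))) stop("grid origin must be finite", call. = FALSE)
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive on all axes", call. = FALSE)
  if (any(dims < 1L)) stop("grid dims must be >= 1 on all axes", call. = FALSE)
  structure(
    list(origin = origin, spacing = spacing, dims = dims, orientation = "axial-LPS"),
    class = "spatial_grid"
  )
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf(
    "<spatial_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, origin (%.1f, %.1f, %.1f) mm\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Test two grids for geometric equality
#'
#' Grids compare equal when origin, spacing and dims agree within `tol` mm.
#'
#' @param a,b `spatial_grid` objects.
#' @param tol Numeric tolerance in mm (default 1e-6).
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "spatial_grid"), inherits(b, "spatial_grid"))
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

# per-axis voxel center coordinates (list of 3 numeric vectors)
axis_centers <- function(grid) {
  lapply(1:3, function(ax) grid$origin[ax] + (seq_len(grid$dims[ax]) - 1) * grid$spacing[ax])
}

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Voxel-center coordinates of a grid
#'
#' @param grid A `spatial_grid`.
#' @return A tibble with columns `i`, `j`, `k` (0-based indices) and
#'   `x`, `y`, `z` (mm) — one row per voxel, in array (column-major) order.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  idx <- expand.grid(
    i = seq_len(grid$dims[1]) - 1L,
    j = seq_len(grid$dims[2]) - 1L,
    k = seq_len(grid$dims[3]) - 1L
  )
  tibble::tibble(
    i = idx$i, j = idx$j, k = idx$k,
    x = grid$origin[1] + idx$i * grid$spacing[1],
    y = grid$origin[2] + idx$j * grid$spacing[2],
    z = grid$origin[3] + idx$k * grid$spacing[3]
  )
}

#' Voxelized structure on a spatial grid
#'
#' @param grid A `spatial_grid`.
#' @param occupancy Logical array with `dim == grid$dims` (or a vector of
#'   matching length), TRUE where the structure occupies the voxel.
#' @param structure_id Character label.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(grid, occupancy, structure_id = "structure") {
  stopifnot(inherits(grid, "spatial_grid"))
  occ <- array(as.logical(occupancy), dim = grid$dims)
  if (length(occ) != prod(grid$dims)) {
    stop("occupancy length must equal product of grid dims", call. = FALSE)
  }
  occ[is.na(occ)] <- FALSE
  structure(
    list(grid = grid, occupancy = occ, structure_id = as.character(structure_id)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask> '%s': %d voxels occupied (%.3f cc) on %d x %d x %d grid\n",
    x$structure_id, sum(x$occupancy), volume_cc(x),
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]
  ))
  invisible(x)
}

#' Empty mask on a grid
#'
#' @param grid A `spatial_grid`.
#' @param structure_id Character label.
#' @return A `structure_mask` with no occupied voxel.
#' @export
empty_mask <- function(grid, structure_id = "empty") {
  structure_mask(grid, array(FALSE, grid$dims), structure_id)
}

#' Absorbed-dose distribution on a spatial grid
#'
#' @param grid A `spatial_grid`.
#' @param values Numeric array (`dim == grid$dims`) of absorbed dose in Gy;
#'   finite and non-negative.
#' @param note Free-text provenance note (e.g. scaling applied on ingest).
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(grid, values, note = "") {
  stopifnot(inherits(grid, "spatial_grid"))
  vals <- array(as.numeric(values), dim = grid$dims)
  if (length(vals) != prod(grid$dims)) {
    stop("dose values length must equal product of grid dims", call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("dose values must be finite", call. = FALSE)
  if (any(vals < 0)) stop("dose values must be non-negative", call. = FALSE)
  structure(list(grid = grid, values = vals, note = as.character(note)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, dose range [%.2f, %.2f] Gy\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Planar contour set for one structure
#'
#' The contour representation used for interchange: closed planar polygons
#' grouped by axial slice position, as an RT structure set stores them. The
#' first vertex of each polygon is implicitly connected to the last.
#'
#' @param structure_id Character label.
#' @param slices List of slices; each slice is `list(z = <mm>, polygons =
#'   list(<n x 2 matrix of (x, y) mm vertices>, ...))` with >= 3 vertices per
#'   polygon.
#' @param color Integer RGB triple in 0..255.
#' @return A `contour_set` object.
#' @export
contour_set <- function(structure_id, slices = list(), color = c(255L, 0L, 0L)) {
  for (s in slices) {
    stopifnot(is.numeric(s$z), is.list(s$polygons))
    for (p in s$polygons) {
      if (!is.matrix(p) || ncol(p) != 2) {
        stop("each polygon must be an n x 2 matrix of (x, y) mm", call. = FALSE)
      }
    }
  }
  structure(
    list(structure_id = as.character(structure_id), slices = slices,
         color = as.integer(color)),
    class = "contour_set"
  )
}

#' @export
print.contour_set <- function(x, ...) {
  npoly <- sum(vapply(x$slices, function(s) length(s$polygons), integer(1)))
  cat(sprintf("<contour_set> '%s': %d polygons on %d slices\n",
              x$structure_id, npoly, length(x$slices)))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' Occupied-voxel count times voxel volume; no partial-volume correction.
#'
#' @param mask A `structure_mask`.
#' @return Volume in cc (cm^3).
#' @examples
#' g <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
#' volume_cc(structure_mask(g, array(TRUE, c(10, 10, 10)))) # 1 cc
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

#' Centroid of a structure
#'
#' Unweighted mean of occupied voxel centers, in patient mm.
#'
#' @param mask A non-empty `structure_mask`.
#' @return Numeric length 3 (x, y, z) in mm.
#' @export
centroid <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop(sprintf("cannot take centroid of empty structure '%s'", mask$structure_id),
         call. = FALSE)
  }
  g <- mask$grid
  c(
    g$origin[1] + mean(idx[, 1] - 1) * g$spacing[1],
    g$origin[2] + mean(idx[, 2] - 1) * g$spacing[2],
    g$origin[3] + mean(idx[, 3] - 1) * g$spacing[3]
  )
}

# axis-aligned bounding box of occupied voxel centers, mm
# returns list(min =, max =) or NULL when empty
mask_bbox <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  g <- mask$grid
  lo <- g$origin + (unname(apply(idx, 2, min)) - 1) * g$spacing
  hi <- g$origin + (unname(apply(idx, 2, max)) - 1) * g$spacing
  list(min = lo, max = hi)
}
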