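# Contour <-> mask conversion.
#
# Rasterization rule: a voxel is occupied iff its center lies inside an odd
# number of the slice's polygons (even-odd rule), so nested polygons punch
# holes. Contour extraction goes through grDevices::contourLines at the 0.5
# level on a zero-padded slice so that re-rasterization reproduces the mask.

# vectorized even-odd point-in-polygon (crossing number).
# px, py: point coordinates; poly: n x 2 vertex matrix (implicitly closed).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a grid
#'
#' Converts a [contour_set()] to a [structure_mask()]. Each slice's polygons
#' are filled with the even-odd rule on voxel centers; a slice is assigned to
#' the nearest grid plane in z and must lie within the grid extent plus one
#' slice spacing.
#'
#' @param contours A `contour_set`.
#' @param grid A `spatial_grid`.
#' @return A `structure_mask` on `grid`. An empty contour set yields an empty
#'   mask with a warning.
#' @export
rasterize_contours <- function(contours, grid) {
  stopifnot(inherits(contours, "contour_set"), inherits(grid, "spatial_grid"))
  occ <- array(FALSE, grid$dims)
  if (length(contours$slices) == 0) {
    warning(sprintf("contour set '%s' has no slices; returning empty mask",
                    contours$structure_id), call. = FALSE)
    return(structure_mask(grid, occ, contours$structure_id))
  }
  ax <- axis_centers(grid)
  zmin <- ax[[3]][1]; zmax <- ax[[3]][grid$dims[3]]
  for (si in seq_along(contours$slices)) {
    s <- contours$slices[[si]]
    if (s$z < zmin - grid$spacing[3] || s$z > zmax + grid$spacing[3]) {
      stop(sprintf("slice %d (z = %.2f mm) lies outside the grid extent", si, s$z),
           call. = FALSE)
    }
    k <- which.min(abs(ax[[3]] - s$z))
    plane <- matrix(FALSE, grid$dims[1], grid$dims[2])
    pts <- expand.grid(x = ax[[1]], y = ax[[2]])
    for (pi in seq_along(s$polygons)) {
      poly <- s$polygons[[pi]]
      if (nrow(poly) < 3) {
        stop(sprintf("polygon %d on slice %d (z = %.2f mm) has fewer than 3 vertices",
                     pi, si, s$z), call. = FALSE)
      }
      plane <- xor(plane, matrix(points_in_polygon(pts$x, pts$y, poly),
                                 grid$dims[1], grid$dims[2]))
    }
    occ[, , k] <- occ[, , k] | plane
  }
  structure_mask(grid, occ, contours$structure_id)
}

#' Extract planar contours from a mask
#'
#' Traces iso-lines at occupancy 0.5 on each axial slice (after zero padding,
#' so border-touching structures close properly). Re-rasterizing the result on
#' the same grid reproduces the input occupancy up to voxels whose centers lie
#' within half a voxel of a contour.
#'
#' @param mask A `structure_mask`.
#' @return A `contour_set`; empty when the mask is empty.
#' @export
mask_to_contours <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  g <- mask$grid
  ax <- axis_centers(g)
  slices <- list()
  for (k in seq_len(g$dims[3])) {
    plane <- mask$occupancy[, , k]
    if (!any(plane)) next
    # pad by one voxel of background on each side
    padded <- matrix(0, g$dims[1] + 2, g$dims[2] + 2)
    padded[2:(g$dims[1] + 1), 2:(g$dims[2] + 1)] <- plane * 1
    xs <- c(ax[[1]][1] - g$spacing[1], ax[[1]], ax[[1]][g$dims[1]] + g$spacing[1])
    ys <- c(ax[[2]][1] - g$spacing[2], ax[[2]], ax[[2]][g$dims[2]] + g$spacing[2])
    cl <- grDevices::contourLines(x = xs, y = ys, z = padded, levels = 0.5)
    polys <- lapply(cl, function(cc) {
      m <- cbind(cc$x, cc$y)
      # drop duplicated closing vertex if present
      if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-9)) m <- m[-nrow(m), , drop = FALSE]
      m
    })
    polys <- polys[vapply(polys, nrow, integer(1)) >= 3]
    if (length(polys) > 0) {
      slices[[length(slices) + 1]] <- list(z = ax[[3]][k], polygons = polys)
    }
  }
  contour_set(mask$structure_id, slices)
}
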