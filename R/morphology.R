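# Euclidean morphology on anisotropic grids.
#
# All margin operations are defined on voxel-center distances: a positive
# margin of d mm occupies every voxel whose center lies within d mm
# (physical Euclidean distance, anisotropy-aware) of an occupied voxel
# center. The workhorse is an exact squared Euclidean distance transform
# computed by per-axis min-convolution with the squared-offset penalty,
# vectorized across the remaining axes. The search radius is capped at
# max_mm: distances <= max_mm are exact, larger ones are reported as Inf.

# one min-convolution pass along the first array dimension:
# out[i, .] = min_j d2[j, .] + ((i - j) * spacing)^2, |i - j| <= max_vox
dt_pass <- function(d2, spacing, max_vox) {
  n <- dim(d2)[1]
  out <- d2
  if (n == 1 || max_vox < 1) return(out)
  flat <- matrix(d2, nrow = n)
  outf <- matrix(out, nrow = n)
  for (o in seq_len(min(max_vox, n - 1))) {
    pen <- (o * spacing)^2
    lo <- 1:(n - o); hi <- (o + 1):n
    outf[hi, ] <- pmin(outf[hi, , drop = FALSE], flat[lo, , drop = FALSE] + pen)
    outf[lo, ] <- pmin(outf[lo, , drop = FALSE], flat[hi, , drop = FALSE] + pen)
  }
  array(outf, dim = dim(d2))
}

#' Euclidean distance map to a structure
#'
#' Distance (mm) from every voxel center to the nearest occupied voxel center
#' of `mask`. Exact up to `max_mm`; voxels farther than `max_mm` get `Inf`.
#' Occupied voxels get 0.
#'
#' @param mask A `structure_mask`.
#' @param max_mm Cap on the search radius in mm (keeps the transform linear in
#'   grid size for the small margins used in planning). Default 60.
#' @return Numeric array of distances in mm, same dims as the grid.
#' @export
distance_map_mm <- function(mask, max_mm = 60) {
  stopifnot(inherits(mask, "structure_mask"), max_mm > 0)
  g <- mask$grid
  d2 <- array(Inf, g$dims)
  d2[mask$occupancy] <- 0
  if (!any(mask$occupancy)) return(array(Inf, g$dims))
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    d2p <- aperm(d2, perm)
    max_vox <- ceiling(max_mm / g$spacing[axis]) + 1L
    d2p <- dt_pass(d2p, g$spacing[axis], max_vox)
    d2 <- aperm(d2p, order(perm))
  }
  d2[d2 > max_mm^2 + 1e-6] <- Inf
  sqrt(d2)
}

#' Expand or contract a structure by a physical margin
#'
#' Positive `distance_mm` dilates: the result occupies every voxel whose
#' center lies within `distance_mm` (Euclidean, mm) of an occupied voxel
#' center. Negative `distance_mm` erodes by the dual rule (a voxel survives
#' iff no unoccupied voxel center lies within `|distance_mm|`). Zero is the
#' identity.
#'
#' @param mask A `structure_mask`.
#' @param distance_mm Signed margin in mm; `|distance_mm|` <= 50.
#' @return A `structure_mask` on the same grid, id suffixed with the margin.
#' @examples
#' g <- spatial_grid(c(-5, -5, -5), c(1, 1, 1), c(11, 11, 11))
#' occ <- array(FALSE, c(11, 11, 11)); occ[6, 6, 6] <- TRUE
#' m <- expand_margin(structure_mask(g, occ, "pt"), 2.5)
#' sum(m$occupancy) # 81
#' @export
expand_margin <- function(mask, distance_mm) {
  stopifnot(inherits(mask, "structure_mask"), is.numeric(distance_mm),
            length(distance_mm) == 1, is.finite(distance_mm))
  if (abs(distance_mm) > 50) {
    stop("margin magnitude exceeds the 50 mm sanity bound", call. = FALSE)
  }
  id <- sprintf("%s%+g mm", mask$structure_id, distance_mm)
  if (distance_mm == 0) {
    return(structure_mask(mask$grid, mask$occupancy, mask$structure_id))
  }
  d <- abs(distance_mm)
  if (distance_mm > 0) {
    if (!any(mask$occupancy)) return(empty_mask(mask$grid, id))
    dm <- distance_map_mm(mask, max_mm = d + max(mask$grid$spacing))
    structure_mask(mask$grid, dm <= d + 1e-9, id)
  } else {
    if (all(mask$occupancy)) return(structure_mask(mask$grid, mask$occupancy, id))
    comp <- structure_mask(mask$grid, !mask$occupancy, "complement")
    dm <- distance_map_mm(comp, max_mm = d + max(mask$grid$spacing))
    structure_mask(mask$grid, mask$occupancy & dm > d + 1e-9, id)
  }
}

#' Ring (shell) around a structure
#'
#' The band of tissue between the `inner_mm` and `outer_mm` expansions of the
#' structure: `expand_margin(mask, outer_mm)` minus
#' `expand_margin(mask, inner_mm)`. With `inner_mm = 0` the ring starts
#' immediately outside the structure and excludes the structure itself.
#'
#' @param mask A `structure_mask`.
#' @param inner_mm Inner margin in mm, >= 0.
#' @param outer_mm Outer margin in mm, > `inner_mm`.
#' @return A `structure_mask` on the same grid.
#' @export
ring <- function(mask, inner_mm, outer_mm) {
  stopifnot(inherits(mask, "structure_mask"), inner_mm >= 0)
  if (outer_mm <= inner_mm) {
    stop("ring outer_mm must exceed inner_mm", call. = FALSE)
  }
  outer <- expand_margin(mask, outer_mm)
  inner <- expand_margin(mask, inner_mm)
  structure_mask(mask$grid, outer$occupancy & !inner$occupancy,
                 sprintf("%s ring %g-%g mm", mask$structure_id, inner_mm, outer_mm))
}

#' Combine structures voxelwise
#'
#' Per-voxel logical combination of masks sharing one grid. `subtraction`
#' removes the union of all later operands from the first; `union`,
#' `intersection` and `xor` fold over all operands.
#'
#' @param operands List of `structure_mask` objects on a common grid (>= 1).
#' @param op One of `"union"`, `"intersection"`, `"subtraction"`, `"xor"`.
#' @param structure_id Label for the result (default derived from `op`).
#' @return A `structure_mask` on the shared grid.
#' @export
boolean_combine <- function(operands, op = c("union", "intersection", "subtraction", "xor"),
                            structure_id = NULL) {
  op <- match.arg(op)
  if (!is.list(operands) || length(operands) == 0) {
    stop("boolean_combine needs at least one operand", call. = FALSE)
  }
  for (m in operands) stopifnot(inherits(m, "structure_mask"))
  g <- operands[[1]]$grid
  for (m in operands[-1]) {
    if (!grid_equal(g, m$grid)) {
      stop(sprintf("operand '%s' lies on a different grid (no implicit resampling)",
                   m$structure_id), call. = FALSE)
    }
  }
  occs <- lapply(operands, function(m) m$occupancy)
  acc <- switch(
    op,
    union = Reduce(`|`, occs),
    intersection = Reduce(`&`, occs),
    xor = Reduce(xor, occs),
    subtraction = {
      if (length(occs) == 1) occs[[1]]
      else occs[[1]] & !Reduce(`|`, occs[-1])
    }
  )
  if (is.null(structure_id)) {
    structure_id <- paste0(op, "(", paste(vapply(operands, function(m) m$structure_id,
                                                 character(1)), collapse = ","), ")")
  }
  structure_mask(g, acc, structure_id)
}
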