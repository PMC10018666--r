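# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's computational paths (distance transform, DP, sorting
# shortcuts) so that agreement is evidence, not tautology.

# -- tiny grid / mask builders ------------------------------------------------

unit_grid <- function(n, spacing = c(1, 1, 1), origin = NULL) {
  n <- rep(n, length.out = 3)
  if (is.null(origin)) origin <- -(n - 1) / 2 * spacing
  spatial_grid(origin, spacing, n)
}

random_mask <- function(grid, p = 0.15, id = "rand") {
  occ <- array(stats::runif(prod(grid$dims)) < p, grid$dims)
  structure_mask(grid, occ, id)
}

cube_mask <- function(grid, lo, hi, id = "cube") {
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])
  inx <- ax[[1]] >= lo[1] & ax[[1]] <= hi[1]
  iny <- ax[[2]] >= lo[2] & ax[[2]] <= hi[2]
  inz <- ax[[3]] >= lo[3] & ax[[3]] <= hi[3]
  occ <- outer(outer(inx, iny, `&`), inz, `&`)
  structure_mask(grid, occ, id)
}

mask_center_points <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  g <- mask$grid
  cbind(g$origin[1] + (idx[, 1] - 1) * g$spacing[1],
        g$origin[2] + (idx[, 2] - 1) * g$spacing[2],
        g$origin[3] + (idx[, 3] - 1) * g$spacing[3])
}

# -- morphology oracle: direct all-pairs Euclidean dilation -------------------

brute_dilate <- function(mask, distance_mm) {
  g <- mask$grid
  occ_pts <- mask_center_points(mask)
  if (nrow(occ_pts) == 0) return(empty_mask(g, mask$structure_id))
  ctr <- as.matrix(grid_centers(g)[, c("x", "y", "z")])
  d2min <- rep(Inf, nrow(ctr))
  for (i in seq_len(nrow(occ_pts))) {
    d2 <- (ctr[, 1] - occ_pts[i, 1])^2 + (ctr[, 2] - occ_pts[i, 2])^2 +
      (ctr[, 3] - occ_pts[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  structure_mask(g, array(d2min <= distance_mm^2 + 1e-9, g$dims), mask$structure_id)
}

# -- DVH metric oracles: direct counting over all candidate thresholds --------

# greatest dose d (scanned over the realized sample values) such that the
# fraction of samples >= d is at least frac
oracle_dose_at_fraction <- function(samples, frac) {
  cands <- sort(unique(samples), decreasing = TRUE)
  best <- min(samples)
  for (d in cands) {
    if (mean(samples >= d) >= frac - 1e-12) return(d)
  }
  best
}

oracle_volume_at_dose <- function(samples, gy) 100 * mean(samples >= gy - 1e-9 * max(1, gy))

# -- exact Wilcoxon oracle: full 2^n enumeration ------------------------------

oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1.0))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# -- shared default phantom (generated once per test run) ---------------------

phantom_cache <- new.env(parent = emptyenv())

get_default_phantom <- function() {
  if (is.null(phantom_cache$phantom)) {
    phantom_cache$phantom <- generate_phantom(phantom_spec())
  }
  phantom_cache$phantom
}

get_default_dose <- function() {
  if (is.null(phantom_cache$dose)) {
    phantom_cache$dose <- generate_dose(get_default_phantom(), dose_model_spec())
  }
  phantom_cache$dose
}

packaged_protocol <- function() {
  parse_clinical_protocol(rtplankit_example("protocols", "ha_wbrt_30gy10fx.xml"))
}

packaged_config <- function() {
  parse_automation_config(rtplankit_example("configs", "ha_wbrt.yaml"))
}

packaged_dictionary <- function() {
  read_structure_dictionary(rtplankit_example("dictionaries", "structures.xml"))
}

# small random dose/mask pair on one grid
random_dose_mask <- function(n = 20, max_gy = 40) {
  g <- unit_grid(n, spacing = c(1.5, 1.5, 2))
  mask <- random_mask(g, p = stats::runif(1, 0.2, 0.6))
  while (sum(mask$occupancy) < 10) mask <- random_mask(g, p = 0.5)
  dose <- dose_grid(g, array(stats::runif(prod(g$dims), 0, max_gy), g$dims))
  list(grid = g, mask = mask, dose = dose)
}
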