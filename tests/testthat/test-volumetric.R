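# Geometry substrate: rasterization, contour extraction, Boolean algebra,
# margins, rings, volumes, centroids.

test_that("rasterization fills polygons by the even-odd rule on voxel centers", {
  g <- spatial_grid(c(0.5, 0.5, 0), c(1, 1, 1), c(20, 20, 1))
  square <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  m <- rasterize_contours(contour_set("sq", list(list(z = 0, polygons = list(square)))), g)
  expect_equal(sum(m$occupancy), 100)

  inner <- matrix(c(3, 3, 7, 3, 7, 7, 3, 7), ncol = 2, byrow = TRUE)
  holed <- rasterize_contours(
    contour_set("holed", list(list(z = 0, polygons = list(square, inner)))), g)
  expect_equal(sum(holed$occupancy), 100 - 16)

  expect_warning(
    empty <- rasterize_contours(contour_set("none", list()), g),
    "no slices"
  )
  expect_equal(sum(empty$occupancy), 0)

  degenerate <- contour_set("bad", list(list(z = 0, polygons = list(square[1:2, ]))))
  expect_error(rasterize_contours(degenerate, g), "fewer than 3 vertices")

  far <- contour_set("far", list(list(z = 50, polygons = list(square))))
  expect_error(rasterize_contours(far, g), "outside the grid extent")
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  set.seed(41)
  g <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(25, 25, 1))
  for (trial in 1:5) {
    k <- sample(5:9, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    r <- stats::runif(k, 3, 11)
    poly <- cbind(12 + r * cos(ang), 12 + r * sin(ang))
    m <- rasterize_contours(contour_set("p", list(list(z = 0, polygons = list(poly)))), g)
    ctr <- expand.grid(x = 0:24, y = 0:24)
    oracle <- pracma::inpolygon(ctr$x, ctr$y, poly[, 1], poly[, 2], boundary = TRUE)
    # centers exactly on edges are convention-dependent; compare off-boundary
    strict <- pracma::inpolygon(ctr$x, ctr$y, poly[, 1], poly[, 2], boundary = FALSE)
    interior_disagreement <- sum(as.vector(m$occupancy[, , 1]) != strict & strict == oracle)
    expect_lte(interior_disagreement, 0)
  }
})

test_that("mask -> contours -> mask round trip reproduces occupancy", {
  g <- unit_grid(16)
  cube <- cube_mask(g, c(-4, -4, -4), c(4, 4, 4))
  rt <- rasterize_contours(mask_to_contours(cube), g)
  expect_identical(rt$occupancy, cube$occupancy)

  expect_length(mask_to_contours(empty_mask(g))$slices, 0)

  # two disjoint cubes on one slice give two polygons on that slice
  g2 <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(20, 20, 1))
  two <- boolean_combine(list(
    cube_mask(g2, c(1, 1, 0), c(5, 5, 0)),
    cube_mask(g2, c(10, 10, 0), c(15, 15, 0))
  ), "union")
  cs <- mask_to_contours(two)
  expect_length(cs$slices, 1)
  expect_length(cs$slices[[1]]$polygons, 2)

  # round trip is idempotent after one cycle on an irregular mask
  set.seed(11)
  rm1 <- expand_margin(random_mask(unit_grid(14), 0.05), 1.6)
  once <- rasterize_contours(mask_to_contours(rm1), rm1$grid)
  twice <- rasterize_contours(mask_to_contours(once), rm1$grid)
  expect_identical(twice$occupancy, once$occupancy)
})

test_that("boolean_combine matches the voxelwise truth table and its algebra", {
  set.seed(7)
  g <- unit_grid(16)
  for (trial in 1:8) {
    a <- random_mask(g, 0.3, "A"); b <- random_mask(g, 0.3, "B")
    c_ <- random_mask(g, 0.3, "C")
    expect_identical(boolean_combine(list(a, b), "union")$occupancy,
                     a$occupancy | b$occupancy)
    expect_identical(boolean_combine(list(a, b), "intersection")$occupancy,
                     a$occupancy & b$occupancy)
    expect_identical(boolean_combine(list(a, b, c_), "subtraction")$occupancy,
                     a$occupancy & !(b$occupancy | c_$occupancy))
    expect_identical(boolean_combine(list(a, b), "xor")$occupancy,
                     xor(a$occupancy, b$occupancy))
    # commutativity / annihilation
    expect_identical(boolean_combine(list(a, b), "union")$occupancy,
                     boolean_combine(list(b, a), "union")$occupancy)
    expect_equal(sum(boolean_combine(list(a, a), "subtraction")$occupancy), 0)
    expect_equal(sum(boolean_combine(list(a, a), "xor")$occupancy), 0)
  }
  expect_identical(boolean_combine(list(a, empty_mask(g)), "union")$occupancy,
                   a$occupancy)
  expect_error(boolean_combine(list(), "union"), "at least one")
  g2 <- spatial_grid(c(1, 0, 0), c(1, 1, 1), c(16, 16, 16))
  expect_error(boolean_combine(list(a, random_mask(g2)), "union"), "different grid")
})

test_that("expand_margin implements center-to-center Euclidean dilation", {
  g <- unit_grid(11)
  occ <- array(FALSE, c(11, 11, 11)); occ[6, 6, 6] <- TRUE
  pt <- structure_mask(g, occ, "pt")
  expect_equal(sum(expand_margin(pt, 2.5)$occupancy), 81)
  expect_equal(sum(expand_margin(empty_mask(g), 5)$occupancy), 0)
  expect_identical(expand_margin(pt, 0)$occupancy, pt$occupancy)
  expect_error(expand_margin(pt, 60), "50 mm")

  # monotone in distance
  set.seed(13)
  m <- random_mask(unit_grid(12, spacing = c(1, 1.5, 2)), 0.1)
  d1 <- expand_margin(m, 2); d2 <- expand_margin(m, 4)
  expect_true(all(d2$occupancy[d1$occupancy]))

  # expand-then-contract a large cube stays within one voxel of the original
  gc <- unit_grid(24)
  cube <- cube_mask(gc, c(-6, -6, -6), c(6, 6, 6))
  back <- expand_margin(expand_margin(cube, 5), -5)
  eroded <- expand_margin(cube, -1.01)
  expect_true(all(back$occupancy[eroded$occupancy]))
})

test_that("ring is the band strictly outside the inner expansion", {
  g <- unit_grid(24)
  cube <- cube_mask(g, c(-4, -4, -4), c(4, 4, 4))
  expect_equal(sum(ring(empty_mask(g), 0, 5)$occupancy), 0)
  r05 <- ring(cube, 0, 5)
  expect_equal(sum(r05$occupancy & cube$occupancy), 0)
  expect_error(ring(cube, 5, 5), "exceed")

  # distance-band oracle on a sphere-ish blob
  blob <- expand_margin(structure_mask(g, {
    occ <- array(FALSE, c(24, 24, 24)); occ[12, 12, 12] <- TRUE; occ
  }, "c"), 4)
  rng <- ring(blob, 2, 5)
  oracle <- boolean_combine(list(brute_dilate(blob, 5), brute_dilate(blob, 2)),
                            "subtraction")
  expect_identical(rng$occupancy, oracle$occupancy)
})

test_that("volume and centroid follow voxel arithmetic", {
  g <- unit_grid(10)
  expect_equal(volume_cc(structure_mask(g, array(TRUE, c(10, 10, 10)))), 1.0)
  expect_equal(volume_cc(empty_mask(g)), 0.0)
  g2 <- spatial_grid(c(0, 0, 0), c(2, 2, 2.5), c(10, 1, 1))
  expect_equal(volume_cc(structure_mask(g2, rep(TRUE, 10))), 0.1)

  # additive over disjoint masks
  a <- cube_mask(g, c(-4, -4, -4), c(-1, -1, -1))
  b <- cube_mask(g, c(1, 1, 1), c(4, 4, 4))
  expect_equal(volume_cc(boolean_combine(list(a, b), "union")),
               volume_cc(a) + volume_cc(b))

  sym <- cube_mask(unit_grid(11), c(-3, -3, -3), c(3, 3, 3))
  expect_equal(centroid(sym), c(0, 0, 0))
  occ <- array(FALSE, c(11, 11, 11)); occ[3, 6, 6] <- TRUE
  one <- structure_mask(unit_grid(11), occ)
  expect_equal(centroid(one), c(-3, 0, 0))
  expect_error(centroid(empty_mask(g)), "empty")
})

test_that("distance transform equals the brute-force oracle on anisotropic grids", {
  set.seed(23)
  for (spec in list(list(n = 8, sp = c(1, 1, 1)),
                    list(n = 16, sp = c(1.2, 0.8, 2.5)),
                    list(n = 24, sp = c(2.5, 2.5, 1)))) {
    g <- unit_grid(spec$n, spacing = spec$sp)
    m <- random_mask(g, 0.08)
    if (!any(m$occupancy)) next
    for (d in c(1.7, 3.3, 6.1)) {
      expect_identical(expand_margin(m, d)$occupancy,
                       brute_dilate(m, d)$occupancy,
                       label = sprintf("n=%d d=%.1f", spec$n, d))
    }
  }
})
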