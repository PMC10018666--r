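# Isocenter placement, field instantiation and jaw fitting.

test_that("isocenter sits at the bounding-box center, rounded to 0.1 mm", {
  g <- unit_grid(21)
  sym <- cube_mask(g, c(-5, -5, -5), c(5, 5, 5))
  expect_equal(place_isocenter(sym), c(0, 0, 0))

  g2 <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(30, 30, 30))
  cube <- cube_mask(g2, c(0, 0, 0), c(20, 10, 6))
  expect_equal(place_isocenter(cube), c(10, 5, 3))

  # oracle: direct min/max scan of occupied centers
  set.seed(3)
  m <- random_mask(unit_grid(15, spacing = c(1.3, 2.1, 0.9)), 0.1)
  pts <- mask_center_points(m)
  expect_equal(place_isocenter(m),
               round((apply(pts, 2, min) + apply(pts, 2, max)) / 2, 1),
               ignore_attr = TRUE)

  expect_error(place_isocenter(empty_mask(g)), "empty")
})

test_that("build_fields mirrors the template: 3 alternating arcs, collimators in order", {
  p <- packaged_protocol()
  layout <- build_fields(p, c(0, -5, 10))
  expect_equal(nrow(layout$fields), 3)
  expect_equal(layout$fields$gantry_start, c(180.1, 179.9, 180.1))
  expect_equal(layout$fields$gantry_stop, c(179.9, 180.1, 179.9))
  expect_equal(layout$fields$rotation, c("CW", "CC", "CW"))
  expect_false(layout$fields$rotation[2] == layout$fields$rotation[1])
  expect_false(layout$fields$rotation[3] == layout$fields$rotation[2])
  expect_equal(layout$fields$collimator, c(345, 15, 90))
  expect_equal(layout$machine_id, "TB1")
  expect_equal(nrow(layout$changes), 0)
})

test_that("machine override is applied and tracked; unknown machines rejected", {
  p <- packaged_protocol()
  layout <- build_fields(p, c(0, 0, 0), machine_id = "TB2")
  expect_equal(layout$machine_id, "TB2")
  expect_equal(nrow(layout$changes), 1)
  expect_equal(layout$changes$parameter, "machine")
  expect_equal(layout$changes$user_value, "TB2")

  expect_error(build_fields(p, c(0, 0, 0), machine_id = "TB9",
                            machine_registry = c("TB1", "TB2")), "unknown machine")
})

test_that("jaws enclose a centered sphere at radius + margin at every angle", {
  g <- unit_grid(55, spacing = c(2, 2, 2))
  occ <- array(FALSE, c(55, 55, 55)); occ[28, 28, 28] <- TRUE
  sphere <- expand_margin(structure_mask(g, occ, "sph"), 50)
  p <- packaged_protocol()
  layout <- fit_all_jaws(build_fields(p, c(0, 0, 0)), sphere, margin_mm = 7)
  for (i in 1:3) {
    f <- layout$fields[i, ]
    expect_equal(f$x2, 57, tolerance = 0.05)   # voxelized sphere radius ~50
    expect_equal(-f$x1, 57, tolerance = 0.05)
    expect_equal(f$y2, 57, tolerance = 0.05)
    expect_equal(-f$y1, 57, tolerance = 0.05)
  }
})

test_that("collimator rotation by 90 degrees swaps jaw extents of an asymmetric target", {
  g <- unit_grid(41)
  slab <- cube_mask(g, c(-15, -3, -6), c(15, 3, 6), "slab")
  field0 <- tibble::tibble(field_id = "F", technique = "static", gantry_start = 0,
                           gantry_stop = 0, rotation = "NONE", collimator = 0,
                           couch = 0, energy = "6X")
  field90 <- dplyr::mutate(field0, collimator = 90)
  j0 <- fit_jaws(slab, field0, c(0, 0, 0), margin_mm = 0)
  j90 <- fit_jaws(slab, field90, c(0, 0, 0), margin_mm = 0)
  expect_equal(j90$x2 - j90$x1, j0$y2 - j0$y1, tolerance = 1e-9)
  expect_equal(j90$y2 - j90$y1, j0$x2 - j0$x1, tolerance = 1e-9)
})

test_that("jaw fitting is monotone in margin and encloses every projected voxel", {
  set.seed(17)
  g <- unit_grid(19, spacing = c(2, 2, 3))
  m <- random_mask(g, 0.05)
  p <- packaged_protocol()
  iso <- place_isocenter(m)
  f <- p$fields[1, ]
  j3 <- fit_jaws(m, f, iso, margin_mm = 3)
  j8 <- fit_jaws(m, f, iso, margin_mm = 8)
  expect_lt(j8$x1, j3$x1); expect_gt(j8$x2, j3$x2)
  expect_lt(j8$y1, j3$y1); expect_gt(j8$y2, j3$y2)

  # enclosure at every sampled angle (margin 0 makes bounds tight)
  j0 <- fit_jaws(m, f, iso, margin_mm = 0, step_deg = 10)
  pts <- mask_center_points(m)
  angles <- seq(0, 350, by = 10)
  for (a in angles) {
    rel <- sweep(pts, 2, iso)
    gr <- a * pi / 180; cr <- f$collimator * pi / 180
    u <- rel[, 1] * cos(gr) + rel[, 2] * sin(gr); v <- rel[, 3]
    uu <- u * cos(cr) + v * sin(cr); vv <- -u * sin(cr) + v * cos(cr)
    expect_true(all(uu >= j0$x1 - 1e-9 & uu <= j0$x2 + 1e-9))
    expect_true(all(vv >= j0$y1 - 1e-9 & vv <= j0$y2 + 1e-9))
  }

  # half-field violation errors
  wide <- cube_mask(unit_grid(45, spacing = c(10, 2, 2)), c(-220, -5, -5), c(220, 5, 5))
  expect_error(fit_jaws(wide, f, c(0, 0, 0), margin_mm = 7), "200 mm")
})

test_that("a single static field yields one field without arc span", {
  xml <- '
<ClinicalProtocol id="static_demo">
  <Prescription totalDoseGy="10" fractions="5" dosePerFractionGy="2" target="PTV"/>
  <Machine id="TB1"/>
  <Fields>
    <Field id="AP" technique="static" gantryStart="0" collimator="0" couch="0" energy="6X"/>
  </Fields>
  <Goals/>
  <ExpectedStructures><Structure id="PTV"/></ExpectedStructures>
</ClinicalProtocol>'
  p <- parse_clinical_protocol(xml)
  layout <- build_fields(p, c(0, 0, 0))
  expect_equal(nrow(layout$fields), 1)
  expect_equal(layout$fields$gantry_start, layout$fields$gantry_stop)
  expect_equal(layout$fields$rotation, "NONE")
})
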