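# DVH computation, dose metrics, normalization, Wilcoxon comparison.

line_dvh <- function(doses) {
  g <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(length(doses), 1, 1))
  compute_dvh(dose_grid(g, doses), structure_mask(g, rep(TRUE, length(doses)), "s"))
}

test_that("DVH metrics reproduce the counting values on 1..100 Gy", {
  dvh <- line_dvh(1:100)
  expect_equal(dose_at_volume(dvh, percent = 95), 6)
  expect_equal(dose_at_volume(dvh, percent = 5), 96)
  expect_equal(dose_at_volume(dvh, percent = 100), 1)   # D100% = minimum
  expect_equal(dose_at_volume(dvh, percent = 2), 99)
  expect_equal(volume_at_dose(dvh, 25), 76)
  expect_equal(volume_at_dose(dvh, 0), 100)
  expect_equal(homogeneity_index(dvh, 50), 100 * (96 - 6) / 50)  # 180

  # Dcc: voxels are 0.001 cc each; hottest 0.005 cc = hottest 5 voxels
  expect_equal(dose_at_volume(dvh, cc = 0.005), 96)
  expect_equal(dose_at_volume(dvh, cc = 0.1), 1)        # whole volume -> min
  expect_error(dose_at_volume(dvh, cc = 0.2), "exceeds")
})

test_that("uniform dose collapses all metrics", {
  dvh <- line_dvh(rep(30, 64))
  expect_equal(dose_at_volume(dvh, percent = 2), 30)
  expect_equal(dose_at_volume(dvh, percent = 98), 30)
  expect_equal(volume_at_dose(dvh, 30), 100)
  expect_equal(volume_at_dose(dvh, 30.01), 0)
  expect_equal(homogeneity_index(dvh, 30), 0)
})

test_that("DVH requires matching grids and non-empty structures; samples concatenate", {
  g <- unit_grid(8)
  dose <- dose_grid(g, array(stats::runif(512, 0, 10), c(8, 8, 8)))
  expect_error(compute_dvh(dose, empty_mask(g)), "empty")
  g2 <- spatial_grid(c(5, 0, 0), c(1, 1, 1), c(8, 8, 8))
  expect_error(compute_dvh(dose, cube_mask(g2, c(5, -2, -2), c(7, 2, 2))),
               "different grids")

  a <- cube_mask(g, c(-3.5, -3.5, -3.5), c(-1, -1, -1), "A")
  b <- cube_mask(g, c(1, 1, 1), c(3.5, 3.5, 3.5), "B")
  u <- boolean_combine(list(a, b), "union")
  expect_equal(sort(compute_dvh(dose, u)$samples),
               sort(c(compute_dvh(dose, a)$samples, compute_dvh(dose, b)$samples)))
})

test_that("all DVH metrics agree with brute-force enumeration on random grids", {
  set.seed(101)
  for (trial in 1:100) {
    rdm <- random_dose_mask(n = 12)
    dvh <- compute_dvh(rdm$dose, rdm$mask)
    s <- rdm$dose$values[rdm$mask$occupancy]
    x <- sample(c(2, 5, 50, 95, 98, 100), 1)
    expect_equal(dose_at_volume(dvh, percent = x),
                 oracle_dose_at_fraction(s, x / 100))
    gy <- stats::runif(1, 0, 40)
    expect_equal(volume_at_dose(dvh, gy), oracle_volume_at_dose(s, gy))
    vcc <- stats::runif(1, 0.5, 1) * dvh$volume_cc
    frac <- vcc / dvh$volume_cc
    expect_equal(dose_at_volume(dvh, cc = vcc),
                 oracle_dose_at_fraction(s, frac - 1e-12))
    rx <- stats::runif(1, 20, 40)
    expect_equal(homogeneity_index(dvh, rx),
                 100 * (oracle_dose_at_fraction(s, 0.05) -
                          oracle_dose_at_fraction(s, 0.95)) / rx)
  }
})

test_that("dose_at_volume and volume_at_dose are near-inverse", {
  set.seed(55)
  rdm <- random_dose_mask(n = 14)
  dvh <- compute_dvh(rdm$dose, rdm$mask)
  for (x in c(1, 2, 5, 20, 50, 80, 95, 99.9, 100)) {
    expect_gte(volume_at_dose(dvh, dose_at_volume(dvh, percent = x)), x - 1e-9)
  }
})

test_that("prescription normalization hits D95 = rx and is idempotent", {
  dvh100 <- line_dvh(1:100)
  g <- spatial_grid(c(0, 0, 0), c(1, 1, 1), c(100, 1, 1))
  dose <- dose_grid(g, 1:100)
  target <- structure_mask(g, rep(TRUE, 100), "t")
  norm <- normalize_prescription(dose, target, rx = 30)
  expect_equal(norm$scale, 5.0)  # D95 was 6
  expect_equal(dose_at_volume(compute_dvh(norm$dose, target), percent = 95), 30)

  again <- normalize_prescription(norm$dose, target, rx = 30)
  expect_equal(again$scale, 1.0, tolerance = 1e-9)

  already <- normalize_prescription(dose_grid(g, rep(30, 100)), target, 30)
  expect_equal(already$scale, 1.0)

  set.seed(77)
  for (trial in 1:25) {
    rdm <- random_dose_mask(n = 10)
    if (max(rdm$dose$values[rdm$mask$occupancy]) == 0) next
    nn <- normalize_prescription(rdm$dose, rdm$mask, rx = 30)
    v30 <- volume_at_dose(compute_dvh(nn$dose, rdm$mask), 30)
    expect_gte(v30, 95)
  }
})

test_that("trilinear resampling is exact on linear fields and ignores out-of-grid", {
  src <- spatial_grid(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  vals <- array(0, c(10, 10, 10))
  ctr <- grid_centers(src)
  vals[] <- 1 + 0.5 * ctr$x + 0.25 * ctr$y + 0.1 * ctr$z
  dose <- dose_grid(src, vals)
  dst <- spatial_grid(c(1, 1, 1), c(2, 2, 2), c(8, 8, 8))
  res <- resample_dose(dose, dst)
  ctr2 <- grid_centers(dst)
  expect_equal(as.vector(res$values), 1 + 0.5 * ctr2$x + 0.25 * ctr2$y + 0.1 * ctr2$z,
               tolerance = 1e-12)
  far <- spatial_grid(c(500, 500, 500), c(2, 2, 2), c(4, 4, 4))
  expect_true(all(resample_dose(dose, far)$values == 0))
})

test_that("exact Wilcoxon matches full 2^n enumeration and stats::wilcox.test", {
  set.seed(202)
  for (trial in 1:40) {
    n <- sample(2:12, 1)
    a <- round(stats::rnorm(n, 0, 2), sample(0:1, 1))  # rounding induces ties/zeros
    b <- round(stats::rnorm(n, 0.5, 2), 1)
    ours <- wilcoxon_signed_rank(a, b)
    oracle <- oracle_wilcoxon(a, b)
    expect_equal(ours$W, oracle$W, label = sprintf("trial %d W", trial))
    expect_equal(ours$p, oracle$p, tolerance = 1e-12,
                 label = sprintf("trial %d p", trial))
  }
  # agreement with the reference implementation when its exact path applies
  for (trial in 1:20) {
    n <- sample(5:12, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)   # continuous: no ties/zeros
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles the documented edge cases and symmetries", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_match(wilcoxon_signed_rank(c(1, 1), c(1, 1))$note, "zero")

  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$W, 15)
  expect_equal(r$p, 0.0625)

  set.seed(9)
  a <- stats::rnorm(8); b <- stats::rnorm(8)
  fwd <- wilcoxon_signed_rank(a, b); rev <- wilcoxon_signed_rank(b, a)
  expect_equal(fwd$p, rev$p)
  n <- fwd$n_effective
  expect_equal(rev$W, n * (n + 1) / 2 - fwd$W)

  # large-n normal path is close to the reference normal approximation
  set.seed(10)
  a <- stats::rnorm(40); b <- stats::rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(a, b)
  expect_equal(ours$method, "normal")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("cohort comparison reports differences and significance", {
  same <- compare_cohorts("D2%", c(30, 31, 32), c(30, 31, 32))
  expect_equal(same$p, 1.0)
  expect_false(same$significant)
  expect_equal(same$mean_difference, 0)

  shift <- compare_cohorts("D2%", 1:10 + 1, 1:10)
  expect_equal(shift$p, 2 / 1024)
  expect_true(shift$significant)

  expect_error(compare_cohorts("x", 1:3, 1:4), "mismatch")

  td <- tidy(shift)
  expect_named(td, c("metric", "n", "mean_a", "sd_a", "mean_b", "sd_b",
                     "mean_difference", "W", "p", "significant"))
  expect_equal(td$mean_difference, 1)
})

test_that("metric evaluation covers goals, bilateral unions and missing structures", {
  g <- unit_grid(16, spacing = c(2, 2, 2))
  ptv <- cube_mask(g, c(-10, -10, -10), c(10, 10, 10), "PTV_3000")
  oar_l <- cube_mask(g, c(-14, -14, -14), c(-12, -12, -12), "OpticNerve_L")
  oar_r <- cube_mask(g, c(12, 12, 12), c(14, 14, 14), "OpticNerve_R")
  vals <- array(10, g$dims)
  vals[ptv$occupancy] <- 30
  vals[oar_r$occupancy] <- 20
  dose <- dose_grid(g, vals)
  masks <- list(PTV_3000 = ptv, OpticNerve_L = oar_l, OpticNerve_R = oar_r)
  goals <- tibble::tibble(
    structure_id = c("PTV_3000", "OpticNerves", "Cochlea"),
    metric = c("D2%", "Dmax", "D2%"),
    comparator = "le", threshold = c(37.5, 30, 10), units = "Gy"
  )
  met <- evaluate_metrics(dose, masks, goals, rx = 30, target_id = "PTV_3000",
                          bilateral_map = list(OpticNerves = c("OpticNerve_L", "OpticNerve_R")))
  expect_equal(nrow(met), 4)   # 3 goals + HI
  expect_equal(met$value[met$structure_id == "PTV_3000" & met$metric == "D2%"], 30)
  # bilateral max comes from the hotter side
  expect_equal(met$value[met$structure_id == "OpticNerves"], 20)
  expect_true(met$flagged[met$structure_id == "Cochlea"])
  expect_equal(met$value[met$metric == "HI"], 0)

  expect_equal(nrow(evaluate_metrics(dose, masks, goals[0, ])), 0)
})

test_that("timing log enforces order and derives the planning endpoints", {
  t0 <- as.POSIXct("2026-09-24 08:00:00", tz = "UTC")
  log <- timing_log()
  log <- log_event(log, "application_start", t0)
  log <- log_event(log, "plan_trigger", t0 + 117)
  log <- log_event(log, "planning_start", t0 + 120)
  log <- log_event(log, "planning_end", t0 + 962)
  s <- timing_summary(log)
  expect_equal(s$tte_s, 117)
  expect_equal(s$tpt_s, 842)
  expect_equal(s$total_s, s$review_lag_s + s$tpt_s)
  expect_gte(s$review_lag_s, 0)
  expect_error(log_event(log, "late", t0 - 1), "earlier")
})
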