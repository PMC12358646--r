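uniform_roi <- function(dose = 60, n = 4, rx = 60) {
  list(grid = dose_grid(array(dose, c(n, n, n)), c(2.5, 2.5, 2.5)),
       roi = roi_mask(array(TRUE, c(n, n, n)), "CTV", "target", rx))
}

test_that("cumulative DVH is a step function for uniform dose", {
  u <- uniform_roi(60)
  cv <- compute_dvh(u$grid, u$roi, bin_width = 0.05)
  expect_equal(cv$volume_fraction[cv$dose_edges <= 60],
               rep(100, sum(cv$dose_edges <= 60)))
  expect_equal(cv$volume_fraction[cv$dose_edges > 60],
               rep(0, sum(cv$dose_edges > 60)))
  expect_equal(cv$volume_fraction[1], 100)                 # edge 0
  expect_equal(cv$volume_fraction[length(cv$volume_fraction)], 0)
  expect_equal(cv$roi_volume_cc, 64 * 0.015625)
  # monotone non-increasing always
  expect_true(all(diff(cv$volume_fraction) <= 0))
})

test_that("DVH volume fractions agree with direct voxel enumeration", {
  vals <- array(0, c(2, 1, 1)); vals[] <- c(50, 70)
  g <- dose_grid(vals, c(1, 1, 1))
  roi <- roi_mask(array(TRUE, c(2, 1, 1)), "x", "oar", 60)
  cv <- compute_dvh(g, roi, bin_width = 1)
  expect_equal(cv$volume_fraction[cv$dose_edges == 60], 50)
  expect_equal(cv$volume_fraction[cv$dose_edges == 50], 100)
  expect_equal(cv$volume_fraction[cv$dose_edges == 70], 50)
  expect_error(compute_dvh(g, roi_mask(array(TRUE, c(3, 1, 1)), "x", "oar", 60)),
               class = "impt_error_lattice_mismatch")
})

test_that("DVH-point metrics match exhaustive enumeration on 1..100 Gy", {
  vals <- array(as.double(1:100), c(100, 1, 1))
  g <- dose_grid(vals, c(2.5, 2.5, 2.5))
  roi <- roi_mask(array(TRUE, c(100, 1, 1)), "x", "oar", 100)
  # D95%: the ceiling(95*100/100)-th largest dose = 95th largest = 6 Gy
  # (95 voxels, doses 6..100, receive at least 6 Gy)
  expect_equal(extract_metric(g, roi, metric_spec("d_percent", 95)), 6)
  expect_equal(extract_metric(g, roi, metric_spec("d_percent", 100)), 1)
  expect_equal(extract_metric(g, roi, metric_spec("d_mean")), mean(1:100))
  # V65%(rx = 100): doses 65..100 -> 36 of 100 voxels
  expect_equal(extract_metric(g, roi, metric_spec("v_percent_rx", 65)), 36)
  # D0.01cc with 0.015625 cc voxels -> single hottest voxel
  expect_equal(extract_metric(g, roi, metric_spec("d_cc", 0.01)), 100)
  # two hottest voxels
  expect_equal(extract_metric(g, roi, metric_spec("d_cc", 0.02)), 99)
  expect_error(extract_metric(g, roi, metric_spec("d_cc", 10)),
               class = "impt_error_volume_exceeds_roi")
})

test_that("uniform ROI metrics are all the uniform dose", {
  u <- uniform_roi(60)
  expect_equal(extract_metric(u$grid, u$roi, metric_spec("d_percent", 95)), 60)
  expect_equal(extract_metric(u$grid, u$roi, metric_spec("d_mean")), 60)
  expect_equal(extract_metric(u$grid, u$roi, metric_spec("v_percent_rx", 90)), 100)
})

test_that("metric labels parse to the expected specs", {
  s <- parse_metric_label("D95%", "lower_is_worse")
  expect_equal(s$kind, "d_percent"); expect_equal(s$parameter, 95)
  expect_equal(parse_metric_label("D0.01cc")$parameter, 0.01)
  expect_equal(parse_metric_label("Dmean")$kind, "d_mean")
  expect_equal(parse_metric_label("V90%")$kind, "v_percent_rx")
  expect_error(parse_metric_label("Q13"), class = "impt_error_bad_metric")
})

test_that("DVH band envelopes bound every member curve", {
  spec <- small_phantom_spec(noise_sd = 0.02)
  set <- generate_scenario_doses(spec, build_scenario_table(5, 3.5))
  ph <- generate_phantom(spec)
  ctv <- ph$masks[[1]]; near <- ph$masks[[2]]
  band <- compute_dvh_band(set, ctv, bin_width = 0.1)
  expect_length(band$curves, 13)
  for (cv in band$curves) {
    expect_true(all(cv$volume_fraction <= band$upper + 1e-12))
    expect_true(all(cv$volume_fraction >= band$lower - 1e-12))
    expect_identical(cv$dose_edges, band$dose_edges)
  }
  # the robust CTV band is far narrower than the abutting OAR band
  expect_lt(band_area(band), band_area(compute_dvh_band(set, near, bin_width = 0.1)))
})

test_that("degenerate scenario set gives a collapsed band", {
  u <- uniform_roi(60)
  set <- degenerate_set(u$grid)
  band <- compute_dvh_band(set, u$roi)
  expect_equal(band$upper, band$lower)
  expect_equal(band_area(band), 0)
})

test_that("band metric summary reports the per-scenario worst value and scenario", {
  # printed worked example: constrictor Dmean across a scenario subset
  vals <- c(nominal = 28.6, U2 = 31.1, U4 = 28.2)
  s <- summarize_band_values(vals, "higher_is_worse")
  expect_equal(s$band_worst, 31.1)
  expect_equal(s$worst_scenario_id, "U2")
  expect_equal(s$bandwidth, 31.1 - 28.2)
  # right parotid: worst scenario differs for a different ROI
  s2 <- summarize_band_values(c(nominal = 21.7, U2 = 18.8, U4 = 27.8),
                              "higher_is_worse")
  expect_equal(s2$band_worst, 27.8)
  expect_equal(s2$worst_scenario_id, "U4")
  # coverage metrics take the minimum
  s3 <- summarize_band_values(c(nominal = 60, U1 = 59.1, U2 = 59.5),
                              "lower_is_worse")
  expect_equal(s3$band_worst, 59.1)
  expect_equal(s3$worst_scenario_id, "U1")
  # ties break toward the lowest scenario index
  s4 <- summarize_band_values(c(nominal = 60, U1 = 61, U2 = 61), "higher_is_worse")
  expect_equal(s4$worst_scenario_id, "U1")
})

test_that("band summary and worst-case metric collapse on a degenerate set", {
  u <- uniform_roi(60)
  set <- degenerate_set(u$grid)
  spec <- metric_spec("d_percent", 95, "lower_is_worse")
  s <- band_metric_summary(set, u$roi, spec)
  expect_equal(s$bandwidth, 0)
  expect_equal(s$band_worst, 60)
  maps <- compute_maps(set)
  expect_equal(worstcase_metric(maps, u$roi, spec), 60)
})

test_that("voxel-wise worst-case DVH dominates every scenario DVH", {
  spec <- small_phantom_spec(seed = 23)
  set <- generate_scenario_doses(spec, build_scenario_table(5, 3.5))
  ph <- generate_phantom(spec)
  maps <- compute_maps(set)
  for (roi in ph$masks[1:2]) {
    band <- compute_dvh_band(set, roi, bin_width = 0.1)
    lo <- compute_dvh(maps$vw_min, roi, edges = band$dose_edges)
    hi <- compute_dvh(maps$vw_max, roi, edges = band$dose_edges)
    expect_true(all(lo$volume_fraction <= band$lower + 1e-12))
    expect_true(all(hi$volume_fraction >= band$upper - 1e-12))
    # hence the metric-level conservativeness, both directions
    d95 <- metric_spec("d_percent", 95, "lower_is_worse")
    dcc <- metric_spec("d_cc", 0.01, "higher_is_worse")
    expect_lte(worstcase_metric(maps, roi, d95),
               band_metric_summary(set, roi, d95)$band_worst)
    expect_gte(worstcase_metric(maps, roi, dcc),
               band_metric_summary(set, roi, dcc)$band_worst)
  }
})

test_that("curve-based estimators agree with exact metrics within one bin", {
  g <- random_grid(c(10, 10, 10), seed = 31, max_dose = 70)
  roi <- roi_mask(array(TRUE, c(10, 10, 10)), "x", "oar", 60)
  bw <- 0.05
  cv <- compute_dvh(g, roi, bin_width = bw)
  for (p in c(2, 50, 95, 98)) {
    exact <- extract_metric(g, roi, metric_spec("d_percent", p))
    curve <- imptrobust:::dose_at_volume_fraction(cv, p)
    expect_lt(abs(exact - curve), bw)
  }
  expect_lt(abs(imptrobust:::mean_from_curve(cv) -
                  extract_metric(g, roi, metric_spec("d_mean"))), bw / 2)
})
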