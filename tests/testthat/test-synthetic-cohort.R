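test_that("nominal phantom dose has the prescribed plateau and logistic tail", {
  spec <- small_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  ctr <- (spec$grid_shape + 1) %/% 2
  # deep inside the CTV the dose is the prescription within 0.5%
  expect_equal(ph$nominal$values[ctr[1], ctr[2], ctr[3]], spec$rx,
               tolerance = 0.005)
  # >= 5 sigma outside the margin surface the dose is < 1% of rx
  d_out <- (spec$ctv_semiaxes[1] + spec$robust_margin +
              5 * spec$penumbra_sigma)
  i_out <- ctr[1] + ceiling(d_out / spec$spacing[1]) + 1
  expect_lt(ph$nominal$values[i_out, ctr[2], ctr[3]], 0.01 * spec$rx)
  # CTV mask rasterized and nonempty, CTV first
  expect_equal(ph$masks[[1]]$name, "CTV")
  expect_equal(ph$masks[[1]]$role, "target")
  expect_gt(sum(ph$masks[[1]]$mask), 0)
})

test_that("phantom generation is bitwise deterministic given the seed", {
  spec <- small_phantom_spec(seed = 5, noise_sd = 0.05)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$nominal$values, b$nominal$values)
  tab <- build_scenario_table(5, 3.5)
  sa <- generate_scenario_doses(spec, tab)
  sb <- generate_scenario_doses(spec, tab)
  for (id in names(sa$doses))
    expect_identical(sa$doses[[id]]$values, sb$doses[[id]]$values)
})

test_that("zero-magnitude scenarios reproduce the nominal dose bitwise", {
  spec <- small_phantom_spec(seed = 3, noise_sd = 0.05)  # noise on
  set <- generate_scenario_doses(spec, build_scenario_table(0, 0))
  for (id in names(set$doses))
    expect_identical(set$doses[[id]]$values, set$nominal$values)
})

test_that("an integer-voxel setup shift translates the dose field exactly", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = c(2.5, 2.5, 2.5),
                       ctv_semiaxes = c(18, 18, 18), rx = 60,
                       robust_margin = 10, penumbra_sigma = 1.5,
                       noise_sd = 0, seed = 2)
  set <- generate_scenario_doses(spec, build_scenario_table(5, 0))
  u1 <- set$doses$U1$values   # shift (+5, 0, 0) = 2 voxels along axis 1
  nom <- set$nominal$values
  expect_equal(u1[3:40, , ], nom[1:38, , ], tolerance = 1e-6)
  u5 <- set$doses$U5$values   # shift (+5, 0, 0) on axis 2
  expect_equal(u5[, 3:40, ], nom[, 1:38, ], tolerance = 1e-6)
})

test_that("positive range uncertainty pushes the distal falloff deeper", {
  spec <- small_phantom_spec(noise_sd = 0)
  tab <- build_scenario_table(0, 3.5)   # pure range perturbations
  set <- generate_scenario_doses(spec, tab)
  plus <- set$doses$U1    # zero shift, +3.5% range
  ctr <- (spec$grid_shape + 1) %/% 2
  edge_mm <- spec$ctv_center[1] + spec$ctv_semiaxes[1] + spec$robust_margin
  i_edge <- round(edge_mm / spec$spacing[1]) + 1
  i_distal <- i_edge + 1                       # ~2 sigma beyond the edge
  i_prox <- i_edge - ceiling(10 / spec$spacing[1])  # 10 mm proximal: plateau
  expect_gt(plus$values[i_distal, ctr[2], ctr[3]],
            set$nominal$values[i_distal, ctr[2], ctr[3]])
  rel <- abs(plus$values[i_prox, ctr[2], ctr[3]] -
               set$nominal$values[i_prox, ctr[2], ctr[3]]) /
    set$nominal$values[i_prox, ctr[2], ctr[3]]
  expect_lt(rel, 0.001)
})

test_that("shifts beyond the grid extent are rejected", {
  spec <- small_phantom_spec(noise_sd = 0)
  expect_error(generate_scenario_doses(spec, build_scenario_table(500, 0)),
               class = "impt_error_bad_input")
})

test_that("cohort generation is reproducible and emits the expected ROIs", {
  a <- generate_cohort(1, "prostate", seed = 77)[[1]]
  b <- generate_cohort(1, "prostate", seed = 77)[[1]]
  expect_identical(a$set$nominal$values, b$set$nominal$values)
  expect_identical(a$rx, b$rx)

  cohort <- generate_cohort(4, "mixed", seed = 13)
  expect_equal(vapply(cohort, `[[`, "", "site"),
               c("prostate", "prostate", "head_neck", "head_neck"))
  roles <- unlist(lapply(cohort, function(p) vapply(p$masks, `[[`, "", "role")))
  expect_gte(sum(roles == "target"), 4)
  expect_gte(sum(roles == "oar"), 8)
  # prostate plans carry 5 mm shifts, head-and-neck 3 mm, both 3.5% range
  shifts <- function(p) max(abs(as.matrix(
    p$scenario_table[, c("shift_lr", "shift_ap", "shift_si")])))
  expect_equal(shifts(cohort[[1]]), 5)
  expect_equal(shifts(cohort[[3]]), 3)
  expect_true(all(vapply(cohort, function(p) all(abs(p$scenario_table$range_pct) == 3.5),
                         logical(1))))
  expect_error(generate_cohort(0), class = "impt_error_bad_input")
})

test_that("robust-optimization emulation keeps scenario CTV D95 within 5% of nominal", {
  cohort <- generate_cohort(4, "mixed", seed = 41)
  d95 <- metric_spec("d_percent", 95, "lower_is_worse")
  for (p in cohort) {
    ctv <- p$masks[[1]]
    vals <- band_metric_summary(p$set, ctv, d95)$values
    expect_gte(min(vals), 0.95 * vals[["nominal"]])
  }
})

test_that("dose variation concentrates in the peri-target gradient shell", {
  cohort <- generate_cohort(2, "mixed", seed = 51)
  for (p in cohort) {
    ebdd <- compute_ebdd(p$set)
    spec <- p$spec
    # scaled-radius distance from the CTV surface (no margin), as in the model
    co <- lapply(1:3, function(a)
      spec$origin[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$spacing[a])
    r2 <- outer(outer(((co[[1]] - spec$ctv_center[1]) / spec$ctv_semiaxes[1])^2,
                      ((co[[2]] - spec$ctv_center[2]) / spec$ctv_semiaxes[2])^2, `+`),
                ((co[[3]] - spec$ctv_center[3]) / spec$ctv_semiaxes[3])^2, `+`)
    d <- (sqrt(r2) - 1) * min(spec$ctv_semiaxes)
    shell <- d >= 5 & d <= 15
    ctv <- p$masks[[1]]$mask
    expect_gt(mean(ebdd$values[shell]), mean(ebdd$values[ctv]))
  }
})

test_that("doubling the setup magnitude does not decrease shell ebDD", {
  spec <- small_phantom_spec(noise_sd = 0)
  shell_mean <- function(setup) {
    set <- generate_scenario_doses(spec, build_scenario_table(setup, 3.5))
    ebdd <- compute_ebdd(set)
    co <- lapply(1:3, function(a)
      spec$origin[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$spacing[a])
    r2 <- outer(outer(((co[[1]] - spec$ctv_center[1]) / spec$ctv_semiaxes[1])^2,
                      ((co[[2]] - spec$ctv_center[2]) / spec$ctv_semiaxes[2])^2, `+`),
                ((co[[3]] - spec$ctv_center[3]) / spec$ctv_semiaxes[3])^2, `+`)
    d <- (sqrt(r2) - 1) * min(spec$ctv_semiaxes)
    mean(ebdd$values[d >= 5 & d <= 15])
  }
  expect_gte(shell_mean(10), shell_mean(5))
})
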