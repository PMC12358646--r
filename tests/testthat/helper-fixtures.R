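# Small in-code fixtures and independent oracles shared across test files.

# Random dose grid on a fixed lattice.
random_grid <- function(shape = c(8, 8, 8), seed = 1, spacing = c(2, 2, 2),
                        origin = c(0, 0, 0), max_dose = 70) {
  set.seed(seed)
  dose_grid(array(runif(prod(shape), 0, max_dose), shape), spacing, origin)
}

# Random scenario set: nominal plus 12 independently perturbed grids.
random_set <- function(shape = c(8, 8, 8), seed = 1) {
  tab <- build_scenario_table(5, 3.5)
  nominal <- random_grid(shape, seed)
  doses <- lapply(1:12, function(i) random_grid(shape, seed * 100 + i))
  assemble_scenario_set(nominal, doses, tab)
}

# Scenario set where every grid equals the nominal.
degenerate_set <- function(nominal = random_grid()) {
  assemble_scenario_set(nominal, rep(list(nominal), 12), build_scenario_table(0, 0))
}

# Independent per-voxel loop oracle for the four robustness maps.
# Deliberately naive: explicit voxel loops, summation in scenario order.
oracle_maps <- function(set, rmsed_mean = TRUE) {
  arrs <- c(list(set$nominal$values), lapply(set$doses, function(g) g$values))
  d <- dim(arrs[[1]])
  ebdd <- rmsed <- vmin <- vmax <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- vapply(arrs, function(a) a[i, j, k], numeric(1))
    vmin[i, j, k] <- min(v)
    vmax[i, j, k] <- max(v)
    ebdd[i, j, k] <- max(v) - min(v)
    ss <- 0
    for (s in 2:13) ss <- ss + (v[1] - v[s])^2
    rmsed[i, j, k] <- if (rmsed_mean) sqrt(ss / 12) else sqrt(ss)
  }
  list(ebdd = ebdd, rmsed = rmsed, vw_min = vmin, vw_max = vmax)
}

# A tiny manually-assembled plan (the structure generate_cohort() emits),
# used to exercise the comparison layer without the full generator.
manual_plan <- function(spec, table, plan_id = "P_manual", site = "manual",
                        metrics = NULL) {
  set <- generate_scenario_doses(spec, table)
  ph <- generate_phantom(spec)
  if (is.null(metrics)) {
    metrics <- c(list(CTV = list(metric_spec("d_percent", 95, "lower_is_worse"))),
                 stats::setNames(lapply(spec$oars, function(o)
                   list(metric_spec("d_mean", direction = "higher_is_worse"))),
                   vapply(spec$oars, `[[`, "", "name")))
  }
  list(plan_id = plan_id, site = site, rx = spec$rx, seed = spec$seed,
       spec = spec, set = set, masks = ph$masks, metrics = metrics,
       scenario_table = table,
       abutting_oar = if (length(spec$oars)) spec$oars[[1]]$name else NA)
}

# A compact phantom with one abutting and one distant OAR.
small_phantom_spec <- function(seed = 11, noise_sd = 0.02,
                               shape = c(40, 40, 40), spacing = c(3, 3, 3)) {
  center <- (shape - 1) / 2 * spacing
  near <- center; near[2] <- near[2] + 20 + 14 - 6 + 10   # straddles the falloff
  far <- center; far[2] <- far[2] - (20 + 14 + 12 + 6)    # low-dose tail
  phantom_spec(grid_shape = shape, spacing = spacing, ctv_center = center,
               ctv_semiaxes = c(20, 20, 20),
               oars = list(
                 list(name = "near_oar", center = near, semiaxes = c(10, 10, 12)),
                 list(name = "far_oar", center = far, semiaxes = c(6, 6, 6))),
               rx = 60, robust_margin = 14, penumbra_sigma = 1,
               beam_axis = 1, noise_sd = noise_sd, seed = seed)
}

# Closed-form Pearson r and two-sided p (t distribution, n-2 df); the
# independent check for the cor.test-based implementation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}
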