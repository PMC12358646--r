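#' Phantom plan specification
#'
#' Describes an analytic stand-in for a robustly optimized IMPT plan: an
#' ellipsoidal CTV receiving a near-uniform prescription dose, a logistic
#' dose falloff anchored to the CTV surface expanded by the robust margin,
#' and a set of ellipsoidal OARs. Scenario doses are later re-evaluated from
#' this analytic model under rigid setup shifts and range scaling, replacing
#' the treatment-planning-system recalculation step.
#'
#' The nominal dose at voxel centre x is `rx * S(d(x)) + noise`, where d is
#' the (scaled-radius) signed distance from the CTV-plus-margin surface
#' (negative inside) and `S(d) = 1 / (1 + exp(d / penumbra_sigma))`, so S is
#' ~1 well inside the expanded target and decays to 0 outside over a few
#' `penumbra_sigma`.
#'
#' @param grid_shape integer length-3 voxel extents.
#' @param spacing voxel size per axis (mm).
#' @param ctv_center CTV centre in mm (physical coordinates).
#' @param ctv_semiaxes CTV ellipsoid semi-axes (mm).
#' @param oars list of OAR descriptors: each a list with `name`,
#'   `center` (mm), `semiaxes` (mm), and optionally `metrics`
#'   (character vector of metric labels such as `"Dmean"`, `"V90%"`).
#' @param rx prescription dose (Gy).
#' @param robust_margin CTV-to-falloff margin (mm). To emulate robust
#'   optimization it should be at least the setup magnitude used to generate
#'   scenarios (plus falloff width and range excursion).
#' @param penumbra_sigma logistic falloff scale (mm).
#' @param beam_axis axis index (1..3) along which range scaling displaces
#'   the distal falloff (single-field emulation; beam travels in the
#'   positive direction, entering at the low grid face).
#' @param noise_sd additive Gaussian dose noise (Gy). One noise field per
#'   plan is drawn from `seed` and shared by the nominal and all scenario
#'   doses, emulating deterministic recalculation texture.
#' @param tilt fractional dose gradient across the plateau per 100 mm along
#'   the beam axis (e.g. 0.03 = 3%/100 mm). Emulates the percent-level
#'   heterogeneity of a real IMPT target dose; it rides with the dose field
#'   under setup shifts, so the CTV sees small but nonzero scenario
#'   variation, as clinical plans do.
#' @param origin physical position of voxel (1,1,1) centre (mm).
#' @param seed RNG seed, recorded in all outputs.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(50, 50, 50), spacing = c(3, 3, 3),
                         ctv_center = NULL, ctv_semiaxes = c(22, 22, 22),
                         oars = list(), rx = 60, robust_margin = 12,
                         penumbra_sigma = 1, beam_axis = 1, noise_sd = 0.02,
                         tilt = 0.02, origin = c(0, 0, 0), seed = 1) {
  grid_shape <- as.integer(grid_shape); spacing <- as.double(spacing)
  impt_check(length(grid_shape) == 3L && all(grid_shape >= 2L),
             "grid_shape must be three extents >= 2", "impt_error_bad_input")
  impt_check(length(spacing) == 3L && all(spacing > 0),
             "spacing must be positive", "impt_error_bad_spacing")
  if (is.null(ctv_center)) ctv_center <- origin + (grid_shape - 1) / 2 * spacing
  impt_check(all(ctv_semiaxes > 0) && robust_margin >= 0 && penumbra_sigma > 0,
             "ctv_semiaxes, robust_margin, penumbra_sigma must be positive",
             "impt_error_bad_input")
  impt_check(noise_sd >= 0, "noise_sd must be >= 0", "impt_error_bad_input")
  impt_check(is.numeric(tilt) && length(tilt) == 1L && abs(tilt) < 0.2,
             "tilt must be a small fractional gradient", "impt_error_bad_input")
  impt_check(beam_axis %in% 1:3, "beam_axis must be 1, 2 or 3",
             "impt_error_bad_input")
  upper <- origin + (grid_shape - 1) * spacing
  impt_check(all(ctv_center - ctv_semiaxes > origin) &&
               all(ctv_center + ctv_semiaxes < upper),
             "CTV extends outside the grid", "impt_error_degenerate_geometry")
  structure(list(grid_shape = grid_shape, spacing = spacing, origin = as.double(origin),
                 ctv_center = as.double(ctv_center),
                 ctv_semiaxes = as.double(ctv_semiaxes),
                 oars = oars, rx = as.double(rx),
                 robust_margin = as.double(robust_margin),
                 penumbra_sigma = as.double(penumbra_sigma),
                 beam_axis = as.integer(beam_axis), noise_sd = as.double(noise_sd),
                 tilt = as.double(tilt), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxel-centre coordinates along one axis.
axis_coords <- function(spec, a) {
  spec$origin[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$spacing[a]
}

# Scaled-radius signed distance (mm) from the surface of an ellipsoid with
# the given center/semiaxes: d = (rho - 1) * min(semiaxes), exact along the
# shortest axis and a monotone underestimate elsewhere. Returns a 3-D array.
ellipsoid_distance <- function(spec, center, semiaxes, shift = c(0, 0, 0),
                               range_delta = 0) {
  comp2 <- vector("list", 3L)
  for (a in 1:3) {
    u <- axis_coords(spec, a) - shift[a] - center[a]
    if (range_delta != 0 && a == spec$beam_axis)
      u <- u - range_delta * (u > 0)  # distal half only; proximal unchanged
    comp2[[a]] <- (u / semiaxes[a])^2
  }
  rho <- sqrt(outer(outer(comp2[[1]], comp2[[2]], `+`), comp2[[3]], `+`))
  (rho - 1) * min(semiaxes)
}

phantom_noise <- function(spec) {
  if (spec$noise_sd == 0) return(0)
  with_local_seed(spec$seed,
    array(stats::rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
          spec$grid_shape))
}

# Analytic dose under one perturbation. `noise` is the per-plan noise field
# (shared across scenarios). Positive range_pct pushes the distal falloff
# deeper along the beam axis by range_pct/100 x depth-to-edge.
analytic_dose <- function(spec, shift = c(0, 0, 0), range_pct = 0, noise = NULL) {
  extent <- (spec$grid_shape - 1) * spec$spacing
  impt_check(all(abs(shift) < extent),
             "shift larger than the grid extent", "impt_error_bad_input")
  A <- spec$ctv_semiaxes + spec$robust_margin
  b <- spec$beam_axis
  depth_to_edge <- (spec$ctv_center[b] + A[b]) - spec$origin[b]
  delta <- range_pct / 100 * depth_to_edge
  d <- ellipsoid_distance(spec, spec$ctv_center, A, shift = shift,
                          range_delta = delta)
  dose <- spec$rx / (1 + exp(d / spec$penumbra_sigma))
  if (spec$tilt != 0) {
    # plateau tilt rides with the shifted dose field (setup only, not range)
    ub <- axis_coords(spec, b) - shift[b] - spec$ctv_center[b]
    dose <- sweep(dose, b, 1 + spec$tilt * ub / 100, `*`)
  }
  if (is.null(noise)) noise <- phantom_noise(spec)
  dose_grid(pmax(dose + noise, 0), spacing = spec$spacing, origin = spec$origin)
}

rasterize_ellipsoid <- function(spec, center, semiaxes) {
  comp2 <- lapply(1:3, function(a) ((axis_coords(spec, a) - center[a]) / semiaxes[a])^2)
  outer(outer(comp2[[1]], comp2[[2]], `+`), comp2[[3]], `+`) <= 1
}

#' Generate the nominal phantom dose and its ROI masks
#'
#' Rasterizes the CTV and OAR ellipsoids by centre-of-voxel inclusion and
#' evaluates the analytic nominal dose. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return List with `nominal` (a [dose_grid]) and `masks` (list of
#'   [roi_mask], CTV first).
#' @export
generate_phantom <- function(spec) {
  impt_check(inherits(spec, "phantom_spec"), "spec must be a phantom_spec",
             "impt_error_bad_input")
  nominal <- analytic_dose(spec)
  ctv <- roi_mask(rasterize_ellipsoid(spec, spec$ctv_center, spec$ctv_semiaxes),
                  name = "CTV", role = "target", rx = spec$rx,
                  spacing = spec$spacing, origin = spec$origin)
  oars <- lapply(spec$oars, function(o)
    roi_mask(rasterize_ellipsoid(spec, o$center, o$semiaxes),
             name = o$name, role = "oar", rx = spec$rx,
             spacing = spec$spacing, origin = spec$origin))
  list(nominal = nominal, masks = c(list(ctv), oars))
}

#' Generate the 12 scenario doses for a phantom plan
#'
#' Each scenario dose is recomputed from the analytic model with (a) the
#' dose field translated by the setup shift (the dose samples the anatomy
#' shifted: scenario dose at x equals the nominal model at x - shift), and
#' (b) the falloff surface displaced along the beam axis by
#' `range_pct/100 x depth-to-edge`. Masks are not moved: evaluation is in
#' the planning anatomy. The per-plan noise field is shared by all
#' scenarios, so zero-magnitude descriptors reproduce the nominal dose
#' bitwise.
#'
#' @param spec a [phantom_spec].
#' @param table descriptor table from [build_scenario_table].
#' @return A `scenario_set` (see [assemble_scenario_set]).
#' @export
generate_scenario_doses <- function(spec, table) {
  noise <- phantom_noise(spec)
  nominal <- analytic_dose(spec, noise = noise)
  doses <- lapply(seq_len(nrow(table)), function(i)
    analytic_dose(spec, shift = scenario_shift(table, i),
                  range_pct = table$range_pct[i], noise = noise))
  assemble_scenario_set(nominal, doses, table)
}

## ---- site profiles and cohort ------------------------------------------------

# Clinical uncertainty settings: 5 mm setup for prostate, 3 mm for head and
# neck, 3.5% range for both. Geometry/prescription ranges are the package's
# documented choice of realistic values (see the methods vignette).
site_profile_settings <- function(site) {
  switch(site,
    prostate = list(
      setup_mm = 5, range_pct = 3.5, robust_margin = 18,
      rx_range = c(36.25, 70), ctv_range = c(18, 25),
      ctv_metrics = "D95%",
      oars = list(
        list(name = "rectum",       gap = -16, axis = 2, sign = +1, skew = c(0, 0, 10),
             semiaxes = c(12, 12, 28), metrics = c("V90%", "V65%")),
        list(name = "bladder",      gap = -10, axis = 2, sign = -1, skew = c(0, 0, -8),
             semiaxes = c(16, 14, 16), metrics = c("V90%", "V65%")),
        list(name = "femoral_head", gap = 12, axis = 1, sign = +1, skew = c(0, 10, 0),
             semiaxes = c(7, 7, 7),  metrics = "Dmean"))),
    head_neck = list(
      setup_mm = 3, range_pct = 3.5, robust_margin = 15,
      rx_range = c(54, 70), ctv_range = c(20, 30),
      ctv_metrics = "D95%",
      oars = list(
        list(name = "constrictor",  gap = -14, axis = 2, sign = +1, skew = c(0, 0, 8),
             semiaxes = c(10, 8, 20),  metrics = "Dmean"),
        list(name = "parotid_r",    gap = -6, axis = 1, sign = +1, skew = c(0, 8, 0),
             semiaxes = c(12, 10, 14), metrics = "Dmean"),
        list(name = "spinal_cord",  gap = 18, axis = 2, sign = -1, skew = c(0, 0, 0),
             semiaxes = c(5, 5, 28),   metrics = "D0.01cc"),
        list(name = "optic_chiasm", gap = 16, axis = 3, sign = +1, skew = c(0, -8, 0),
             semiaxes = c(6, 6, 4),    metrics = "D0.01cc"))),
    impt_abort(sprintf("unknown site profile: %s", site), "impt_error_bad_input"))
}

# Build one randomized phantom_spec for a site. `gap` is the distance (mm)
# from the CTV-plus-margin surface to the OAR's nearest surface along the
# placement axis; negative gaps straddle the falloff (high-dose OARs).
sample_plan_spec <- function(site, plan_seed) {
  prof <- site_profile_settings(site)
  with_local_seed(plan_seed, {
    semi <- stats::runif(3, prof$ctv_range[1], prof$ctv_range[2])
    rx <- round(stats::runif(1, prof$rx_range[1], prof$rx_range[2]), 2)
    tilt <- stats::runif(1, 0.02, 0.05)   # percent-level plateau heterogeneity
    shape <- c(50L, 50L, 50L); spacing <- c(3, 3, 3)
    center <- (shape - 1) / 2 * spacing
    oars <- lapply(prof$oars, function(o) {
      dist <- semi[o$axis] + prof$robust_margin + o$gap + o$semiaxes[o$axis]
      ctr <- center + (o$skew %||% c(0, 0, 0))  # diagonal placement: different
      ctr[o$axis] <- ctr[o$axis] + o$sign * dist  # scenarios dominate different ends
      list(name = o$name, center = ctr, semiaxes = o$semiaxes,
           metrics = o$metrics)
    })
    phantom_spec(grid_shape = shape, spacing = spacing, ctv_center = center,
                 ctv_semiaxes = semi, oars = oars, rx = rx,
                 robust_margin = prof$robust_margin, penumbra_sigma = 3,
                 beam_axis = 1, noise_sd = 0.02, tilt = tilt, seed = plan_seed)
  })
}

#' Generate a synthetic cohort of phantom plans
#'
#' Emulates (not reproduces) a clinical cohort: per-plan randomized CTV
#' geometry and prescription, site-specific uncertainty settings (5 mm setup
#' for prostate, 3 mm for head and neck, 3.5% range for both), and an OAR
#' set containing at least one abutting (high-dose) and one distant
#' (low-dose) structure per plan. All randomness derives from `seed` via the
#' documented per-plan derivation `(seed * 10007 + plan index) mod (2^31 - 1)`,
#' so distinct root seeds give fully distinct cohorts.
#'
#' @param n_plans number of plans (>= 1).
#' @param site_profile `"prostate"`, `"head_neck"`, or `"mixed"` (first half
#'   prostate, second half head and neck).
#' @param seed root RNG seed.
#' @return List of plans; each plan is a list with `plan_id`, `site`, `rx`,
#'   `seed`, `spec`, `set` (a `scenario_set`), `masks` (list of [roi_mask]),
#'   `metrics` (named list of [metric_spec] lists per ROI), `scenario_table`,
#'   and `abutting_oar` (name of the high-dose OAR).
#' @export
generate_cohort <- function(n_plans, site_profile = c("mixed", "prostate", "head_neck"),
                            seed = 1) {
  site_profile <- match.arg(site_profile)
  impt_check(is.numeric(n_plans) && length(n_plans) == 1L && n_plans >= 1,
             "n_plans must be >= 1", "impt_error_bad_input")
  n_plans <- as.integer(n_plans)
  sites <- switch(site_profile,
    prostate = rep("prostate", n_plans),
    head_neck = rep("head_neck", n_plans),
    mixed = rep(c("prostate", "head_neck"), c(ceiling(n_plans / 2), floor(n_plans / 2))))
  lapply(seq_len(n_plans), function(i) {
    site <- sites[i]
    prof <- site_profile_settings(site)
    plan_seed <- as.integer((as.numeric(seed) * 10007 + i) %% 2147483647)
    spec <- sample_plan_spec(site, plan_seed)
    table <- build_scenario_table(prof$setup_mm, prof$range_pct)
    set <- generate_scenario_doses(spec, table)
    ph <- generate_phantom(spec)
    metrics <- c(list(CTV = lapply(prof$ctv_metrics, parse_metric_label,
                                   direction = "lower_is_worse")),
                 stats::setNames(
                   lapply(spec$oars, function(o)
                     lapply(o$metrics, parse_metric_label,
                            direction = "higher_is_worse")),
                   vapply(spec$oars, `[[`, "", "name")))
    list(plan_id = sprintf("P%02d_%s", i, site), site = site, rx = spec$rx,
         seed = plan_seed, spec = spec, set = set, masks = ph$masks,
         metrics = metrics, scenario_table = table,
         abutting_oar = prof$oars[[1]]$name)
  })
}
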