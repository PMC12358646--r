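#' Per-voxel robustness maps
#'
#' The four per-voxel robustness fields derived from a scenario set, with
#' scenario index i = 0 the nominal dose and i = 1..12 the uncertainty
#' scenarios:
#'
#' * **ebDD** (error-bar dose distribution): `max_i D_i - min_i D_i` over
#'   i = 0..12 — the per-voxel range of dose across scenarios.
#' * **RMSED** (root-mean-square error dose):
#'   `sqrt( (1/12) * sum_{i=1..12} (D_0 - D_i)^2 )` — the per-voxel RMS
#'   deviation of the scenario doses from nominal (nominal excluded from the
#'   sum). With `mean = FALSE` the 1/12 factor is dropped (root-sum-square),
#'   which rescales every voxel by a constant `sqrt(12)` and cannot change
#'   any correlation or ranking.
#' * **voxel-wise min / max**: per-voxel extrema over i = 0..12 (nominal
#'   included). Generally not physically realizable doses, since different
#'   voxels may take their extremum in different scenarios.
#'
#' @param set a `scenario_set` from [assemble_scenario_set] or
#'   [generate_scenario_doses].
#' @param mean logical; divide the RMSED sum of squares by 12 before the
#'   square root (default `TRUE`).
#' @return `compute_ebdd`, `compute_rmsed` return a [dose_grid];
#'   `compute_voxelwise_extrema` returns `list(vw_min, vw_max)`;
#'   `compute_maps` returns a `robustness_maps` object with fields `ebdd`,
#'   `rmsed`, `vw_min`, `vw_max`, `n_scenarios`,
#'   `includes_nominal_in_extrema`, `rmsed_mean`.
#' @examples
#' tab <- build_scenario_table(0, 0)
#' g <- dose_grid(array(60, c(4, 4, 4)), c(2, 2, 2))
#' set <- assemble_scenario_set(g, rep(list(g), 12), tab)
#' max(compute_ebdd(set)$values)  # 0: identical grids
#' @name robustness_maps
NULL

as_set_arrays <- function(set) {
  impt_check(inherits(set, "scenario_set"), "expected a scenario_set",
             "impt_error_bad_input")
  lapply(scenario_grids(set), function(g) g$values)
}

#' @rdname robustness_maps
#' @export
compute_ebdd <- function(set) {
  arrs <- as_set_arrays(set)
  vmax <- Reduce(pmax, arrs)
  vmin <- Reduce(pmin, arrs)
  dose_grid(vmax - vmin, set$nominal$spacing, set$nominal$origin)
}

#' @rdname robustness_maps
#' @export
compute_rmsed <- function(set, mean = TRUE) {
  arrs <- as_set_arrays(set)
  nom <- arrs[[1]]
  ss <- Reduce(`+`, lapply(arrs[-1], function(a) (nom - a)^2))
  if (mean) ss <- ss / (length(arrs) - 1L)
  dose_grid(sqrt(ss), set$nominal$spacing, set$nominal$origin)
}

#' @rdname robustness_maps
#' @export
compute_voxelwise_extrema <- function(set) {
  arrs <- as_set_arrays(set)
  list(vw_min = dose_grid(Reduce(pmin, arrs), set$nominal$spacing, set$nominal$origin),
       vw_max = dose_grid(Reduce(pmax, arrs), set$nominal$spacing, set$nominal$origin))
}

#' @rdname robustness_maps
#' @export
compute_maps <- function(set, mean = TRUE) {
  ext <- compute_voxelwise_extrema(set)
  ebdd <- compute_ebdd(set)
  rmsed <- compute_rmsed(set, mean = mean)
  nom <- set$nominal$values
  ok <- all(ext$vw_min$values <= nom) && all(nom <= ext$vw_max$values) &&
    identical(ebdd$values, ext$vw_max$values - ext$vw_min$values) &&
    all(ebdd$values >= 0) && all(rmsed$values >= 0)
  if (!ok)
    impt_abort("robustness map invariants violated (internal consistency)",
               "impt_error_internal_consistency")
  structure(list(ebdd = ebdd, rmsed = rmsed,
                 vw_min = ext$vw_min, vw_max = ext$vw_max,
                 n_scenarios = length(set$doses),
                 includes_nominal_in_extrema = TRUE, rmsed_mean = mean),
            class = "robustness_maps")
}

#' @export
print.robustness_maps <- function(x, ...) {
  cat(sprintf("<robustness_maps> %s voxels; max ebDD %.3g Gy, max RMSED %.3g Gy\n",
              paste(dim(x$ebdd$values), collapse = "x"),
              max(x$ebdd$values), max(x$rmsed$values)))
  invisible(x)
}

#' Write the four robustness maps as volumes
#'
#' Emits `<prefix>_ebdd`, `_rmsed`, `_vwmin`, `_vwmax` volumes via
#' [write_volume].
#'
#' @param maps a `robustness_maps` object.
#' @param prefix output path prefix (directory must exist).
#' @param format `"nrrd"` or `"nifti"`.
#' @return Character vector of the four paths, invisibly.
#' @export
write_maps <- function(maps, prefix, format = c("nrrd", "nifti")) {
  format <- match.arg(format)
  ext <- if (format == "nrrd") ".nrrd" else ".nii.gz"
  fields <- c(ebdd = "ebdd", rmsed = "rmsed", vwmin = "vw_min", vwmax = "vw_max")
  paths <- character(0)
  for (suffix in names(fields)) {
    p <- paste0(prefix, "_", suffix, ext)
    write_volume(maps[[fields[[suffix]]]], p, format)
    paths <- c(paths, p)
  }
  invisible(paths)
}
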