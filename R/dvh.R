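#' DVH metric specification
#'
#' Describes one DVH-point evaluation metric:
#'
#' * `d_percent` — dose received by at least `parameter` percent of the ROI
#'   volume (e.g. D95%), computed exactly as the `ceiling(p*N/100)`-th
#'   largest voxel dose.
#' * `d_cc` — dose to the hottest `parameter` cc (e.g. D0.01cc), computed as
#'   the `ceiling(v / voxel_volume)`-th hottest voxel (conservative ceiling
#'   rule, no sub-voxel interpolation).
#' * `d_mean` — arithmetic mean of in-ROI voxel doses.
#' * `v_percent_rx` — percent of ROI volume receiving at least
#'   `parameter` percent of the prescription dose (e.g. V90%).
#'
#' `direction` states which extreme is clinically worst: `lower_is_worse`
#' for target coverage (CTV D95%), `higher_is_worse` for all OAR metrics.
#'
#' @param kind one of `"d_percent"`, `"d_cc"`, `"d_mean"`, `"v_percent_rx"`.
#' @param parameter percent volume (`d_percent`), cc (`d_cc`), or
#'   percent-of-Rx threshold (`v_percent_rx`); ignored for `d_mean`.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @param label display label; a conventional one (e.g. `"D95%"`) is built
#'   when omitted.
#' @return Object of class `metric_spec`.
#' @examples
#' metric_spec("d_percent", 95, "lower_is_worse")
#' parse_metric_label("V90%", "higher_is_worse")
#' @export
metric_spec <- function(kind = c("d_percent", "d_cc", "d_mean", "v_percent_rx"),
                        parameter = NULL,
                        direction = c("higher_is_worse", "lower_is_worse"),
                        label = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind != "d_mean")
    impt_check(is.numeric(parameter) && length(parameter) == 1L && parameter > 0,
               sprintf("metric kind '%s' needs a positive parameter", kind),
               "impt_error_bad_metric")
  if (is.null(label))
    label <- switch(kind,
                    d_percent = sprintf("D%g%%", parameter),
                    d_cc = sprintf("D%gcc", parameter),
                    d_mean = "Dmean",
                    v_percent_rx = sprintf("V%g%%", parameter))
  structure(list(kind = kind, parameter = parameter, direction = direction,
                 label = label),
            class = "metric_spec")
}

#' @rdname metric_spec
#' @param text a conventional metric label: `"D95%"`, `"D0.01cc"`,
#'   `"Dmean"`, `"V90%"`.
#' @export
parse_metric_label <- function(text, direction = c("higher_is_worse", "lower_is_worse")) {
  direction <- match.arg(direction)
  if (grepl("^Dmean$", text, ignore.case = TRUE))
    return(metric_spec("d_mean", direction = direction))
  m <- regmatches(text, regexec("^D([0-9.]+)%$", text))[[1]]
  if (length(m)) return(metric_spec("d_percent", as.numeric(m[2]), direction))
  m <- regmatches(text, regexec("^D([0-9.]+)cc$", text))[[1]]
  if (length(m)) return(metric_spec("d_cc", as.numeric(m[2]), direction))
  m <- regmatches(text, regexec("^V([0-9.]+)%$", text))[[1]]
  if (length(m)) return(metric_spec("v_percent_rx", as.numeric(m[2]), direction))
  impt_abort(sprintf("cannot parse metric label: %s", text), "impt_error_bad_metric")
}

# Survival (cumulative-descending) volume fraction at each edge: percent of
# `values` that are >= edge. Exact: no binning error.
survival_fraction <- function(values, edges) {
  s <- sort(values)
  n <- length(s)
  100 * (n - findInterval(edges, s, left.open = TRUE)) / n
}

# Ascending edges from 0 past `upper` in steps of bin_width; the final edge
# strictly exceeds `upper` so the curve reaches 0 there.
dose_edges <- function(upper, bin_width) {
  impt_check(is.numeric(bin_width) && length(bin_width) == 1L && bin_width > 0,
             "bin_width must be positive", "impt_error_bad_input")
  seq(0, by = bin_width, length.out = floor(upper / bin_width) + 2L)
}

#' Cumulative dose-volume histogram
#'
#' Standard cumulative (dose-descending) DVH: `volume_fraction(d)` is the
#' percent of ROI voxels receiving at least dose `d`, evaluated exactly at
#' each bin edge (the binning only discretizes the dose axis, not the
#' counts).
#'
#' @param dose a [dose_grid].
#' @param roi a [roi_mask] on the same lattice.
#' @param bin_width dose bin width in Gy (default 0.05).
#' @param scenario_id label stored on the curve.
#' @param edges optional explicit dose edges (used to place a family of
#'   curves on shared edges).
#' @return Object of class `dvh_curve`: list with `dose_edges` (Gy),
#'   `volume_fraction` (percent, monotone non-increasing, 100 at dose 0),
#'   `roi_volume_cc`, `scenario_id`.
#' @export
compute_dvh <- function(dose, roi, bin_width = 0.05, scenario_id = "nominal",
                        edges = NULL) {
  v <- roi_doses(dose, roi)
  if (is.null(edges)) edges <- dose_edges(max(v), bin_width)
  structure(list(dose_edges = edges,
                 volume_fraction = survival_fraction(v, edges),
                 roi_volume_cc = sum(roi$mask) * voxel_volume_cc(dose),
                 scenario_id = scenario_id),
            class = "dvh_curve")
}

#' Extract a DVH-point metric from a dose grid
#'
#' Dx% and Dcc are computed from exact sorted voxel doses, not from a binned
#' curve, so headline metrics carry no bin-width sensitivity.
#'
#' @param dose a [dose_grid].
#' @param roi a [roi_mask]; its `rx` supplies the prescription for
#'   `v_percent_rx` metrics.
#' @param spec a [metric_spec].
#' @return The metric value: Gy for dose metrics, percent of ROI volume for
#'   `v_percent_rx`.
#' @examples
#' g <- dose_grid(array(60, c(4, 4, 4)), c(2.5, 2.5, 2.5))
#' roi <- roi_mask(array(TRUE, c(4, 4, 4)), "CTV", "target", rx = 60)
#' extract_metric(g, roi, metric_spec("d_percent", 95, "lower_is_worse"))
#' @export
extract_metric <- function(dose, roi, spec) {
  impt_check(inherits(spec, "metric_spec"), "spec must be a metric_spec",
             "impt_error_bad_metric")
  v <- roi_doses(dose, roi)
  n <- length(v)
  switch(spec$kind,
    d_percent = {
      impt_check(spec$parameter <= 100, "percent volume must be <= 100",
                 "impt_error_bad_metric")
      k <- ceiling(spec$parameter * n / 100)
      sort(v, decreasing = TRUE)[max(k, 1L)]
    },
    d_cc = {
      vv <- voxel_volume_cc(dose)
      impt_check(spec$parameter <= n * vv,
                 sprintf("requested volume %g cc exceeds ROI volume %g cc",
                         spec$parameter, n * vv),
                 "impt_error_volume_exceeds_roi")
      k <- ceiling(spec$parameter / vv)
      sort(v, decreasing = TRUE)[max(k, 1L)]
    },
    d_mean = mean(v),
    v_percent_rx = 100 * mean(v >= spec$parameter / 100 * roi$rx))
}

#' DVH band across the nominal and 12 uncertainty scenarios
#'
#' Computes the family of 13 cumulative DVHs on shared dose edges (spanning
#' 0 to the global maximum dose across scenarios) plus the pointwise
#' upper/lower envelope curves.
#'
#' @param set a `scenario_set`.
#' @param roi a [roi_mask].
#' @param bin_width dose bin width (Gy).
#' @return Object of class `dvh_band`: list with `curves` (named list of 13
#'   [compute_dvh] curves, `nominal` first), `upper`, `lower` (percent
#'   envelopes), `dose_edges`.
#' @export
compute_dvh_band <- function(set, roi, bin_width = 0.05) {
  grids <- scenario_grids(set)
  gmax <- max(vapply(grids, function(g) max(roi_doses(g, roi)), numeric(1)))
  edges <- dose_edges(gmax, bin_width)
  curves <- lapply(names(grids), function(id)
    compute_dvh(grids[[id]], roi, bin_width, scenario_id = id, edges = edges))
  names(curves) <- names(grids)
  vfs <- vapply(curves, `[[`, numeric(length(edges)), "volume_fraction")
  structure(list(curves = curves,
                 upper = apply(vfs, 1, max), lower = apply(vfs, 1, min),
                 dose_edges = edges),
            class = "dvh_band")
}

#' Area between the DVH band envelopes
#'
#' Trapezoidal integral of `(upper - lower)` over dose, with volume as a
#' fraction (0-1), so units are Gy. A wider band means the ROI's DVH is more
#' sensitive to the uncertainty scenarios.
#'
#' @param band a `dvh_band`.
#' @return Band area in Gy.
#' @export
band_area <- function(band) {
  gap <- (band$upper - band$lower) / 100
  sum(diff(band$dose_edges) * (gap[-1] + gap[-length(gap)]) / 2)
}

#' Summarize one metric across the 13 scenarios (physical-scenario worst case)
#'
#' Evaluates the metric on the nominal and each scenario dose, then reports
#' the bandwidth (max - min of the 13 values) and the band-worst value: the
#' minimum for `lower_is_worse` metrics (coverage) or the maximum for
#' `higher_is_worse` metrics (OARs). This is the physical-scenario worst
#' case: the worst value attained by a single realizable scenario.
#'
#' @param set a `scenario_set`.
#' @param roi a [roi_mask].
#' @param spec a [metric_spec].
#' @return List with `values` (13 named metric values, nominal first),
#'   `bandwidth`, `band_worst`, `worst_scenario_id` (ties broken toward the
#'   lowest scenario index, nominal counting as index 0).
#' @export
band_metric_summary <- function(set, roi, spec) {
  grids <- scenario_grids(set)
  values <- vapply(grids, extract_metric, numeric(1), roi = roi, spec = spec)
  c(list(values = values), summarize_band_values(values, spec$direction))
}

#' @rdname band_metric_summary
#' @param values named numeric vector of per-scenario metric values (names
#'   are scenario ids in index order, nominal first). Exposed so printed
#'   per-scenario values can be summarized directly.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @export
summarize_band_values <- function(values, direction = c("higher_is_worse",
                                                        "lower_is_worse")) {
  direction <- match.arg(direction)
  impt_check(is.numeric(values) && length(values) >= 1 && !is.null(names(values)),
             "values must be a named numeric vector", "impt_error_bad_input")
  worst_idx <- if (direction == "lower_is_worse") which.min(values) else which.max(values)
  list(bandwidth = max(values) - min(values),
       band_worst = unname(values[worst_idx]),
       worst_scenario_id = names(values)[worst_idx])
}

#' Metric from the voxel-wise worst-case distribution
#'
#' Evaluates the metric on the voxel-wise minimum dose when the metric is
#' coverage-type (`lower_is_worse`) and on the voxel-wise maximum when it is
#' OAR-type (`higher_is_worse`). Because the voxel-wise extrema bound every
#' scenario dose voxel-by-voxel, this value is always at least as
#' conservative as the physical-scenario worst case.
#'
#' @param maps a `robustness_maps` object from [compute_maps].
#' @param roi a [roi_mask].
#' @param spec a [metric_spec].
#' @return The metric value.
#' @export
worstcase_metric <- function(maps, roi, spec) {
  grid <- if (spec$direction == "lower_is_worse") maps$vw_min else maps$vw_max
  extract_metric(grid, roi, spec)
}

## Curve-based estimators, used to bound the effect of binning on the exact
## voxel-based metrics (consistency properties), and for plotting exports.

# Largest dose edge whose volume fraction is still >= p percent.
dose_at_volume_fraction <- function(curve, p) {
  ok <- curve$volume_fraction >= p
  if (!any(ok)) return(curve$dose_edges[1])
  max(curve$dose_edges[ok])
}

# Mean dose from the differential histogram implied by the cumulative curve,
# using bin midpoints; agrees with the voxel mean within bin_width/2.
mean_from_curve <- function(curve) {
  f <- -diff(curve$volume_fraction) / 100
  mids <- (curve$dose_edges[-1] + curve$dose_edges[-length(curve$dose_edges)]) / 2
  sum(f * mids)
}

#' Export a DVH band as a long-format data frame
#'
#' One row per (scenario, dose edge), suitable for CSV export and external
#' plotting.
#'
#' @param band a `dvh_band`.
#' @param roi_name ROI name column value.
#' @return data.frame with columns `roi`, `scenario_id`, `dose_gy`,
#'   `volume_pct`.
#' @export
band_to_long <- function(band, roi_name = "ROI") {
  do.call(rbind, lapply(band$curves, function(cv) data.frame(
    roi = roi_name, scenario_id = cv$scenario_id,
    dose_gy = cv$dose_edges, volume_pct = cv$volume_fraction,
    stringsAsFactors = FALSE)))
}
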