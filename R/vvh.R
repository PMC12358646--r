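#' Error-bar / RMSED volume histogram (EVH / RVH)
#'
#' Cumulative-descending histogram of the per-voxel variation values (ebDD
#' or RMSED) inside an ROI: `volume_fraction(e)` is the percent of ROI
#' volume whose variation is at least `e` Gy. Construction is identical to a
#' DVH, but over variation dose rather than dose.
#'
#' @param map a [dose_grid] holding an ebDD or RMSED field.
#' @param roi a [roi_mask].
#' @param source `"ebdd"` or `"rmsed"`, recorded on the histogram.
#' @param bin_width error-dose bin width (Gy). The default (0.01) is finer
#'   than the usual DVH dose bin because variation values are typically an
#'   order of magnitude smaller than doses; a robust target's in-ROI
#'   variation must still span several bins for its AUC to be meaningful.
#' @return Object of class `vvh`: list with `source`, `error_edges` (Gy),
#'   `volume_fraction` (percent), `auc` (Gy).
#' @examples
#' tab <- build_scenario_table(0, 0)
#' g <- dose_grid(array(60, c(4, 4, 4)), c(2, 2, 2))
#' set <- assemble_scenario_set(g, rep(list(g), 12), tab)
#' roi <- roi_mask(array(TRUE, c(4, 4, 4)), "CTV", "target", rx = 60)
#' compute_vvh(compute_ebdd(set), roi, "ebdd")$auc  # 0: no variation
#' @export
compute_vvh <- function(map, roi, source = c("ebdd", "rmsed"), bin_width = 0.01) {
  source <- match.arg(source)
  v <- roi_doses(map, roi)
  edges <- vvh_edges(max(v), bin_width)
  h <- structure(list(source = source, error_edges = edges,
                      volume_fraction = survival_fraction(v, edges),
                      auc = NA_real_),
                 class = "vvh")
  h$auc <- vvh_auc(h)
  h
}

# Edges in bin_width steps whose upper integration limit is exactly the max
# in-ROI variation, so a uniform map integrates to its value and a zero map
# to 0 (unlike DVH edges, which extend one bin past the max dose).
vvh_edges <- function(upper, bin_width) {
  impt_check(is.numeric(bin_width) && length(bin_width) == 1L && bin_width > 0,
             "bin_width must be positive", "impt_error_bad_input")
  base <- seq(0, by = bin_width, length.out = max(ceiling(upper / bin_width), 1L))
  unique(c(base, upper))
}

#' Area under an EVH/RVH curve
#'
#' Trapezoidal integral over the error axis with volume expressed as a
#' fraction (0-1), so the AUC is in Gy and comparable across ROIs of
#' different volume. By the survival-function identity the AUC equals the
#' ROI-mean variation, up to a discretization error bounded by
#' `bin_width/2`. A smaller AUC indicates less variation across scenarios.
#'
#' @param h a `vvh` from [compute_vvh].
#' @param percent_axis logical; if `TRUE`, integrate with the volume axis in
#'   percent (multiplies the AUC by 100).
#' @return AUC in Gy (or Gy-percent when `percent_axis`).
#' @export
vvh_auc <- function(h, percent_axis = FALSE) {
  impt_check(inherits(h, "vvh"), "h must be a vvh", "impt_error_bad_input")
  f <- h$volume_fraction / 100
  auc <- sum(diff(h$error_edges) * (f[-1] + f[-length(f)]) / 2)
  if (percent_axis) 100 * auc else auc
}

#' Export an EVH/RVH curve as a data frame
#'
#' @param h a `vvh`.
#' @param roi_name ROI name column value.
#' @return data.frame with columns `roi`, `source`, `error_gy`, `volume_pct`.
#' @export
vvh_to_long <- function(h, roi_name = "ROI") {
  data.frame(roi = roi_name, source = h$source,
             error_gy = h$error_edges, volume_pct = h$volume_fraction,
             stringsAsFactors = FALSE)
}
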