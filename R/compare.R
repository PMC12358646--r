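#' Normalize a dose to percent of prescription
#'
#' @param value dose in Gy.
#' @param rx prescription dose in Gy (> 0).
#' @return `100 * value / rx`.
#' @examples
#' normalize_to_rx(28.6, 56)  # 51.07% -> high-dose group
#' @export
normalize_to_rx <- function(value, rx) {
  impt_check(is.numeric(rx) && all(rx > 0), "rx must be > 0", "impt_error_bad_rx")
  100 * value / rx
}

# Evaluate all five methods for every (roi, metric) of one plan. Returns one
# data.frame row per (roi, metric).
evaluate_plan <- function(plan, bin_width = 0.05, vvh_bin_width = 0.01,
                          rmsed_mean = TRUE) {
  set <- plan$set
  maps <- compute_maps(set, mean = rmsed_mean)
  rows <- list()
  for (roi in plan$masks) {
    specs <- plan$metrics[[roi$name]]
    if (is.null(specs)) next
    evh <- compute_vvh(maps$ebdd, roi, "ebdd", vvh_bin_width)
    rvh <- compute_vvh(maps$rmsed, roi, "rmsed", vvh_bin_width)
    nominal_dmean <- extract_metric(set$nominal, roi, metric_spec("d_mean"))
    for (spec in specs) {
      band <- band_metric_summary(set, roi, spec)
      vw <- worstcase_metric(maps, roi, spec)
      nominal <- unname(band$values[["nominal"]])
      is_dose <- spec$kind != "v_percent_rx"
      # %Rx scale for dose-valued metrics; V-metrics are already percent volume
      to_pct <- function(x) if (is_dose) normalize_to_rx(x, plan$rx) else x
      # grouping uses the nominal value for dose metrics, nominal Dmean for
      # volume metrics (a volume percent is not comparable to 50% Rx)
      group_basis <- if (is_dose) nominal else nominal_dmean
      dose_group <- if (roi$role == "target") "target"
        else if (normalize_to_rx(group_basis, plan$rx) >= 50) "high" else "low"
      rows[[length(rows) + 1L]] <- data.frame(
        plan_id = plan$plan_id, site = plan$site, roi = roi$name,
        role = roi$role, metric = spec$label, kind = spec$kind,
        direction = spec$direction, unit = if (is_dose) "Gy" else "%vol",
        rx = plan$rx, dose_group = dose_group,
        nominal = nominal, vw_worst = vw, band_worst = band$band_worst,
        worst_scenario = band$worst_scenario_id, bandwidth = band$bandwidth,
        nominal_pct = to_pct(nominal), vw_worst_pct = to_pct(vw),
        band_worst_pct = to_pct(band$band_worst),
        bandwidth_pct = if (is_dose) normalize_to_rx(band$bandwidth, plan$rx)
                        else band$bandwidth,
        evh_auc = evh$auc, rvh_auc = rvh$auc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the per-(plan, ROI, metric) method-comparison table
#'
#' Joins the five method outputs — EVH AUC, RVH AUC, DVH bandwidth,
#' voxel-wise worst-case and physical-scenario worst-case — into one row per
#' (plan, roi, metric). Dose-valued columns are additionally normalized to
#' percent of the plan prescription (`*_pct` columns); each OAR row is
#' assigned to a low-dose (<50% Rx) or high-dose (>=50% Rx) group from its
#' nominal-scenario value (nominal Dmean of the ROI for volume-valued
#' metrics).
#'
#' @param cohort a cohort from [generate_cohort] (or a list of plans with
#'   the same structure).
#' @param bin_width DVH dose bin width (Gy).
#' @param vvh_bin_width EVH/RVH error-dose bin width (Gy); finer than the
#'   DVH bin since per-voxel variations are much smaller than doses.
#' @param rmsed_mean divide the RMSED sum of squares by 12 (see
#'   [compute_rmsed]).
#' @return A data.frame of class `method_table`; no missing cells.
#' @export
build_method_table <- function(cohort, bin_width = 0.05, vvh_bin_width = 0.01,
                               rmsed_mean = TRUE) {
  tbl <- do.call(rbind, lapply(cohort, evaluate_plan, bin_width = bin_width,
                               vvh_bin_width = vvh_bin_width,
                               rmsed_mean = rmsed_mean))
  num <- c("nominal", "vw_worst", "band_worst", "bandwidth",
           "evh_auc", "rvh_auc", "nominal_pct", "vw_worst_pct", "band_worst_pct")
  if (anyNA(tbl[num]))
    impt_abort("method table has missing cells", "impt_error_internal_consistency")
  class(tbl) <- c("method_table", "data.frame")
  tbl
}

method_columns <- c("evh_auc", "rvh_auc", "bandwidth_pct",
                    "vw_worst_pct", "band_worst_pct")

#' Pairwise Pearson correlations between the five evaluation methods
#'
#' All 10 pairwise Pearson coefficients with two-sided p-values
#' (t-distribution, n - 2 df) within one stratum (CTV rows or OAR rows), as
#' in a method-comparison correlation matrix. Dose-valued columns enter on
#' the %Rx scale; Pearson r is invariant to that per-column rescaling. A
#' constant column yields a flagged result (`flag = "constant"`, r = NA)
#' rather than a silent NaN. Holm-adjusted p-values are emitted alongside
#' the unadjusted ones for completeness.
#'
#' @param table a `method_table` from [build_method_table].
#' @param stratum `"ctv"` or `"oar"`.
#' @return data.frame with columns `stratum`, `var1`, `var2`, `r`, `p`,
#'   `p_holm`, `n`, `flag`.
#' @export
pearson_matrix <- function(table, stratum = c("ctv", "oar")) {
  stratum <- match.arg(stratum)
  rows <- table[table$role == (if (stratum == "ctv") "target" else "oar"), ]
  impt_check(nrow(rows) >= 3, sprintf("stratum '%s' needs >= 3 rows", stratum),
             "impt_error_bad_count")
  pairs <- utils::combn(method_columns, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    x <- rows[[pairs[1, j]]]; y <- rows[[pairs[2, j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(stratum = stratum, var1 = pairs[1, j], var2 = pairs[2, j],
                 r = NA_real_, p = NA_real_, n = length(x), flag = "constant",
                 stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      data.frame(stratum = stratum, var1 = pairs[1, j], var2 = pairs[2, j],
                 r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 flag = "", stringsAsFactors = FALSE)
    }
  }))
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out[c("stratum", "var1", "var2", "r", "p", "p_holm", "n", "flag")]
}

#' Conservativeness of the voxel-wise worst case vs the DVH band worst
#'
#' For CTV coverage the voxel-wise minimum can only lower D95%, so the
#' paired difference `band_worst - vw_worst` (in %Rx) is expected >= 0; for
#' OAR metrics the voxel-wise maximum can only raise the value, so
#' `vw_worst - band_worst` is expected >= 0. Reports box-plot quartiles of
#' the paired difference per stratum (CTV, OAR low-dose group, OAR
#' high-dose group), pairing on identical (plan, roi, metric) keys.
#'
#' @param table a `method_table`.
#' @return data.frame with columns `group`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max` (differences in %Rx, or percent volume for V-metrics).
#' @export
summarize_conservativeness <- function(table) {
  impt_check(any(table$role == "target"), "no target rows present",
             "impt_error_empty_stratum")
  diff_pct <- ifelse(table$role == "target",
                     table$band_worst_pct - table$vw_worst_pct,
                     table$vw_worst_pct - table$band_worst_pct)
  group <- ifelse(table$role == "target", "ctv",
                  paste0("oar_", table$dose_group))
  do.call(rbind, lapply(split(diff_pct, group), function(d) {
    q <- stats::quantile(d, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(n = length(d), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  })) -> out
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
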