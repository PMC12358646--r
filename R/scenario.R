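#' Build the 12-scenario setup/range uncertainty table
#'
#' Enumerates the standard worst-case evaluation grid: for each anatomical
#' axis (L/R, A/P, S/I) the setup shift is applied with both signs, and each
#' shifted position is combined with both signs of the range uncertainty.
#' There are no pure-range and no diagonal-shift scenarios. Ordering is
#' frozen (U1 = (+setup, 0, 0, +range), U2 = (+setup, 0, 0, -range), U3 =
#' (-setup, 0, 0, +range), ..., U12 = (0, 0, -setup, -range)) because
#' scenario ids are load-bearing in reports (the worst scenario is named).
#'
#' Positive shift means the positive direction along the named grid axis;
#' only the symmetry of the 12-point grid matters for the evaluation layer.
#'
#' @param setup_mm setup uncertainty magnitude in mm (>= 0); clinically 5 mm
#'   for prostate and 3 mm for head and neck.
#' @param range_pct range uncertainty magnitude in percent (>= 0);
#'   clinically 3.5.
#' @return A data frame with 12 rows and columns `id`, `shift_lr`,
#'   `shift_ap`, `shift_si` (mm) and `range_pct` (%).
#' @examples
#' build_scenario_table(5, 3.5)
#' @export
build_scenario_table <- function(setup_mm, range_pct = 3.5) {
  impt_check(is.numeric(setup_mm) && length(setup_mm) == 1L && setup_mm >= 0,
             "setup_mm must be a single non-negative magnitude (mm)",
             "impt_error_bad_magnitude")
  impt_check(is.numeric(range_pct) && length(range_pct) == 1L && range_pct >= 0,
             "range_pct must be a single non-negative magnitude (%)",
             "impt_error_bad_magnitude")
  shift <- matrix(0, nrow = 12, ncol = 3)
  rng <- numeric(12)
  k <- 0L
  for (axis in 1:3) for (ssign in c(1, -1)) for (rsign in c(1, -1)) {
    k <- k + 1L
    shift[k, axis] <- ssign * setup_mm
    rng[k] <- rsign * range_pct
  }
  data.frame(id = paste0("U", 1:12),
             shift_lr = shift[, 1], shift_ap = shift[, 2], shift_si = shift[, 3],
             range_pct = rng, stringsAsFactors = FALSE)
}

scenario_shift <- function(table, i) {
  as.double(table[i, c("shift_lr", "shift_ap", "shift_si")])
}

#' Assemble a validated scenario set
#'
#' Bundles the nominal dose with the 12 scenario doses and their uncertainty
#' descriptors. All 13 grids must share one lattice; no resampling is
#' performed — a mismatch is an error, because every downstream map is
#' defined voxel-by-voxel across scenarios.
#'
#' @param nominal the nominal [dose_grid] (scenario index 0).
#' @param doses list of 12 [dose_grid]s, ordered U1..U12.
#' @param table descriptor table from [build_scenario_table] (12 rows with
#'   unique ids).
#' @return Object of class `scenario_set`: list with `nominal`, `doses`
#'   (named list U1..U12) and `table`.
#' @export
assemble_scenario_set <- function(nominal, doses, table) {
  impt_check(inherits(nominal, "dose_grid"), "nominal must be a dose_grid",
             "impt_error_bad_input")
  impt_check(length(doses) == 12L,
             sprintf("expected 12 scenario doses, got %d", length(doses)),
             "impt_error_bad_count")
  impt_check(is.data.frame(table) && nrow(table) == 12L,
             sprintf("expected 12 scenario descriptors, got %d",
                     if (is.data.frame(table)) nrow(table) else 0L),
             "impt_error_bad_count")
  impt_check(!anyDuplicated(table$id), "duplicate scenario ids",
             "impt_error_duplicate_ids")
  for (i in seq_along(doses)) {
    impt_check(inherits(doses[[i]], "dose_grid"),
               "every scenario dose must be a dose_grid", "impt_error_bad_input")
    assert_same_lattice(nominal, doses[[i]],
                        sprintf("nominal and scenario %s grids", table$id[i]))
  }
  names(doses) <- table$id
  structure(list(nominal = nominal, doses = doses, table = table),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> nominal + %d scenarios (%s), %s voxels\n",
              length(x$doses), paste(range(x$table$id), collapse = ".."),
              paste(dim(x$nominal$values), collapse = "x")))
  invisible(x)
}

# All 13 dose grids in index order: nominal (i = 0) first, then U1..U12.
scenario_grids <- function(set) c(list(nominal = set$nominal), set$doses)

#' Write / read scenario descriptors as a YAML config
#'
#' Serializes the 12 descriptors as a list of `{id, shift_mm, range_pct}`
#' entries.
#'
#' @param table descriptor table from [build_scenario_table].
#' @param path YAML file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns the descriptor data frame.
#' @export
write_scenario_config <- function(table, path) {
  entries <- lapply(seq_len(nrow(table)), function(i) list(
    id = table$id[i],
    shift_mm = as.double(scenario_shift(table, i)),
    range_pct = table$range_pct[i]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  impt_check(file.exists(path), sprintf("file not found: %s", path),
             "impt_error_missing_file")
  entries <- yaml::read_yaml(path)
  impt_check(length(entries) == 12L, "expected 12 scenario entries",
             "impt_error_bad_count")
  do.call(rbind, lapply(entries, function(e) data.frame(
    id = e$id, shift_lr = e$shift_mm[1], shift_ap = e$shift_mm[2],
    shift_si = e$shift_mm[3], range_pct = e$range_pct,
    stringsAsFactors = FALSE)))
}
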