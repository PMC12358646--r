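#' Dose grid
#'
#' A dense 3-D scalar dose field in Gy on a regular voxel lattice. The axis
#' convention is fixed: axis 1 = left/right (L/R), axis 2 =
#' anterior/posterior (A/P), axis 3 = superior/inferior (S/I), matching the
#' order in which setup-uncertainty shifts are specified.
#'
#' @param values 3-D numeric array of dose values (Gy); must be finite and
#'   non-negative.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel (1,1,1).
#' @return An object of class `dose_grid`: a list with elements `values`,
#'   `spacing`, `origin`.
#' @examples
#' g <- dose_grid(array(1, c(4, 4, 4)), spacing = c(2.5, 2.5, 2.5))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    impt_abort("not a 3-D volume", "impt_error_not_3d")
  values <- array(as.double(values), dim(values))  # drop foreign attributes
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  impt_check(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
             "spacing must be three strictly positive finite values (mm)",
             "impt_error_bad_spacing")
  impt_check(length(origin) == 3L && all(is.finite(origin)),
             "origin must be three finite values (mm)", "impt_error_bad_origin")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    impt_abort("dose values must be finite and non-negative",
               "impt_error_invalid_dose")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels @ %s mm, origin (%s) mm, dose range [%.4g, %.4g] Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a dose grid in cubic centimetres
#'
#' @param grid a `dose_grid` or `roi_mask`.
#' @return Scalar voxel volume in cc (`prod(spacing)/1000`).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

grid_shape <- function(grid) dim(if (inherits(grid, "roi_mask")) grid$mask else grid$values)

#' Test whether two grids share one lattice
#'
#' Shape must match exactly; spacing and origin within `tol` mm. No
#' resampling is ever performed by this package: scenario doses and masks
#' that do not share a lattice are rejected.
#'
#' @param a,b `dose_grid` objects (or `roi_mask` for shape-only checks).
#' @param tol tolerance in mm for spacing/origin agreement.
#' @return `TRUE` or `FALSE`.
#' @export
same_lattice <- function(a, b, tol = 1e-6) {
  if (!identical(grid_shape(a), grid_shape(b))) return(FALSE)
  sa <- a$spacing %||% NULL; sb <- b$spacing %||% NULL
  oa <- a$origin %||% NULL; ob <- b$origin %||% NULL
  if (is.null(sa) || is.null(sb)) return(TRUE)  # masks carry no metadata
  all(abs(sa - sb) <= tol) && all(abs(oa - ob) <= tol)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_same_lattice <- function(a, b, what = "grids") {
  impt_check(same_lattice(a, b),
             sprintf("%s do not share one lattice (shape/spacing/origin)", what),
             "impt_error_lattice_mismatch")
}

#' ROI mask
#'
#' Boolean 3-D mask aligned to a companion dose grid, carrying the ROI name,
#' its role (`target` or `oar`) and the owning plan's prescription dose.
#'
#' @param mask 3-D logical array (or numeric; nonzero = inside). Must contain
#'   at least one voxel.
#' @param name ROI name.
#' @param role `"target"` or `"oar"`.
#' @param rx prescription dose of the owning plan (Gy, > 0).
#' @param spacing,origin optional lattice metadata (mm), used for volume
#'   computations and lattice checks when available.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, name, role = c("target", "oar"), rx,
                     spacing = NULL, origin = NULL) {
  role <- match.arg(role)
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    impt_abort("mask is not a 3-D volume", "impt_error_not_3d")
  mask <- array(as.logical(mask), dim(mask))
  impt_check(!anyNA(mask), "mask contains NA", "impt_error_invalid_mask")
  impt_check(any(mask), sprintf("ROI '%s' is empty", name), "impt_error_empty_roi")
  impt_check(is.numeric(rx) && length(rx) == 1L && is.finite(rx) && rx > 0,
             "rx must be a single positive dose (Gy)", "impt_error_bad_rx")
  structure(list(mask = mask, name = as.character(name), role = role,
                 rx = as.double(rx),
                 spacing = if (!is.null(spacing)) as.double(spacing),
                 origin = if (!is.null(origin)) as.double(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s), %d voxels, rx = %g Gy\n",
              x$name, x$role, sum(x$mask), x$rx))
  invisible(x)
}

#' ROI volume in cc
#'
#' @param roi a `roi_mask` with lattice metadata, or supply `grid`.
#' @param grid optional companion `dose_grid` providing the voxel volume.
#' @return ROI volume in cc.
#' @export
roi_volume_cc <- function(roi, grid = NULL) {
  vv <- if (!is.null(grid)) voxel_volume_cc(grid)
        else if (!is.null(roi$spacing)) prod(roi$spacing) / 1000
        else impt_abort("no spacing available to compute ROI volume",
                        "impt_error_bad_spacing")
  sum(roi$mask) * vv
}

#' Extract an axial (S/I) slice from a dose grid
#'
#' Returns the 2-D dose matrix at one superior/inferior position, suitable
#' for external colourwash plotting. Values are unchanged.
#'
#' @param grid a `dose_grid`.
#' @param index slice index along axis 3 (1-based, `1 <= index <= dim3`).
#' @return A 2-D numeric matrix (L/R by A/P).
#' @export
extract_axial_slice <- function(grid, index) {
  n3 <- dim(grid$values)[3]
  impt_check(is.numeric(index) && length(index) == 1L && index == as.integer(index) &&
               index >= 1 && index <= n3,
             sprintf("slice index out of range [1, %d]", n3),
             "impt_error_index_out_of_range")
  grid$values[, , as.integer(index)]
}

# Dose values restricted to an ROI, after a lattice/shape check.
roi_doses <- function(dose, roi) {
  impt_check(identical(dim(dose$values), dim(roi$mask)),
             "dose grid and ROI mask shapes differ", "impt_error_lattice_mismatch")
  if (!is.null(roi$spacing)) assert_same_lattice(dose, roi, "dose grid and ROI mask")
  dose$values[roi$mask]
}
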