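#' Read a dose or mask volume
#'
#' Supported formats: NRRD (raw or ascii encoding, little/big endian), NIfTI-1
#' (via RNifti), and DICOM RT Dose (read-only; uncompressed implicit/explicit
#' VR little endian; pixel values are scaled into Gy by the file's
#' DoseGridScaling factor). Format is inferred from the file extension when
#' `format = "auto"`.
#'
#' @param path path to the volume file.
#' @param format one of `"auto"`, `"nrrd"`, `"nifti"`, `"dicom_rtdose"`.
#' @return A [dose_grid] with spacing/origin taken from the file metadata.
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti", "dicom_rtdose")) {
  format <- match.arg(format)
  impt_check(file.exists(path), sprintf("file not found: %s", path),
             "impt_error_missing_file")
  if (format == "auto") {
    format <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom_rtdose"
      else impt_abort(sprintf("cannot infer format from extension: %s", path),
                      "impt_error_unknown_format")
  }
  switch(format,
         nrrd = read_nrrd(path),
         nifti = read_nifti_grid(path),
         dicom_rtdose = read_dicom_rtdose(path))
}

#' Write a dose or mask volume
#'
#' Emits a file that round-trips through [read_volume] with bitwise-equal
#' values and spacing/origin equal within 1e-9 mm. NRRD files carry the axis
#' convention (axis1=L/R, axis2=A/P, axis3=S/I) in a header comment.
#'
#' @param grid a [dose_grid].
#' @param path destination path.
#' @param format `"auto"` (from extension), `"nrrd"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  impt_check(inherits(grid, "dose_grid"), "grid must be a dose_grid",
             "impt_error_bad_input")
  if (anyNA(grid$values) || any(!is.finite(grid$values)))
    impt_abort("grid contains non-finite values; refusing to write",
               "impt_error_invalid_dose")
  if (format == "auto") {
    format <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else impt_abort(sprintf("cannot infer format from extension: %s", path),
                      "impt_error_unknown_format")
  }
  if (!dir.exists(dirname(path)))
    impt_abort(sprintf("directory does not exist: %s", dirname(path)),
               "impt_error_unwritable_path")
  switch(format, nrrd = write_nrrd(grid, path), nifti = write_nifti_grid(grid, path))
  invisible(path)
}

#' Read an ROI mask volume
#'
#' Reads a label volume (nonzero = inside) and attaches ROI metadata.
#'
#' @inheritParams read_volume
#' @inheritParams roi_mask
#' @return A [roi_mask] aligned to the volume's lattice.
#' @export
read_mask <- function(path, name, role = c("target", "oar"), rx,
                      format = c("auto", "nrrd", "nifti", "dicom_rtdose")) {
  g <- read_volume(path, match.arg(format))
  roi_mask(g$values != 0, name = name, role = match.arg(role), rx = rx,
           spacing = g$spacing, origin = g$origin)
}

## ---- NRRD ------------------------------------------------------------------
## Minimal NRRD implementation (detached headers are not supported): the
## package writes raw-encoded little-endian doubles and reads raw/ascii
## encodings of the common scalar types.

write_nrrd <- function(grid, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) impt_abort(
                    sprintf("cannot open for writing: %s", path),
                    "impt_error_unwritable_path"))
  on.exit(close(con))
  d <- dim(grid$values)
  hdr <- c(
    "NRRD0004",
    "# axis convention: axis1=L/R, axis2=A/P, axis3=S/I",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space: left-posterior-superior",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.double(grid$values), con, size = 8L, endian = "little")
  invisible(path)
}

nrrd_field <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\s*:"), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^", key, "\\s*:"), "", hit[1]))
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), "[,\\s]+")[[1]]))
}

read_nrrd <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(0x0a))
  # header ends at the first blank line (\n\n, possibly with \r)
  hdr_end <- NA_integer_
  for (k in seq_along(nl)[-1]) {
    gap <- nl[k] - nl[k - 1]
    if (gap == 1L || (gap == 2L && raw[nl[k] - 1] == as.raw(0x0d))) {
      hdr_end <- nl[k]; break
    }
  }
  impt_check(!is.na(hdr_end), "malformed NRRD header (no blank line)",
             "impt_error_bad_header")
  lines <- strsplit(gsub("\r", "", rawToChar(raw[1:hdr_end])), "\n")[[1]]
  impt_check(grepl("^NRRD", lines[1]), "not an NRRD file", "impt_error_bad_header")
  lines <- lines[!grepl("^\\s*#", lines)]

  dimension <- as.integer(nrrd_field(lines, "dimension"))
  if (!identical(dimension, 3L))
    impt_abort("not a 3-D volume", "impt_error_not_3d")
  sizes <- as.integer(strsplit(nrrd_field(lines, "sizes"), "\\s+")[[1]])
  impt_check(length(sizes) == 3L && all(sizes > 0), "bad sizes field",
             "impt_error_bad_header")
  type <- tolower(nrrd_field(lines, "type"))
  encoding <- tolower(nrrd_field(lines, "encoding") %||% "raw")
  endian <- tolower(nrrd_field(lines, "endian") %||% "little")

  spacing <- NULL; origin <- c(0, 0, 0)
  sd <- nrrd_field(lines, "space directions")
  if (!is.null(sd)) {
    vecs <- parse_nrrd_vectors(sd)
    impt_check(length(vecs) == 3L, "bad space directions", "impt_error_bad_header")
    spacing <- vapply(seq_len(3), function(a) {
      v <- vecs[[a]]
      impt_check(all(abs(v[-a]) < 1e-12),
                 "non-axis-aligned space directions are not supported",
                 "impt_error_bad_header")
      v[a]
    }, numeric(1))
  }
  sp <- nrrd_field(lines, "spacings")
  if (is.null(spacing) && !is.null(sp))
    spacing <- as.numeric(strsplit(sp, "\\s+")[[1]])
  impt_check(!is.null(spacing) && all(is.finite(spacing)) && all(spacing > 0),
             "non-positive or missing spacing", "impt_error_bad_spacing")
  so <- nrrd_field(lines, "space origin")
  if (!is.null(so)) origin <- parse_nrrd_vectors(so)[[1]]

  n <- prod(sizes)
  payload <- raw[(hdr_end + 1):length(raw)]
  values <- switch(encoding,
    raw = {
      spec <- switch(type,
        "double" = list(what = "double", size = 8L),
        "float"  = list(what = "double", size = 4L),
        "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L),
        "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L),
        "ushort" = , "uint16" = , "unsigned short" =
          list(what = "integer", size = 2L, signed = FALSE),
        "uchar" = , "uint8" = , "unsigned char" =
          list(what = "integer", size = 1L, signed = FALSE),
        impt_abort(sprintf("unsupported NRRD type: %s", type),
                   "impt_error_bad_header"))
      as.double(readBin(payload, spec$what, n = n, size = spec$size,
                        signed = spec$signed %||% TRUE,
                        endian = if (endian == "big") "big" else "little"))
    },
    ascii = , text = , txt =
      as.double(scan(text = rawToChar(payload), quiet = TRUE, n = n)),
    impt_abort(sprintf("unsupported NRRD encoding: %s", encoding),
               "impt_error_bad_header"))
  impt_check(length(values) == n, "truncated NRRD payload", "impt_error_bad_header")
  dose_grid(array(values, sizes), spacing = spacing, origin = origin)
}

## ---- NIfTI (via RNifti) ----------------------------------------------------

write_nifti_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { arr <- arr[, , , 1]; d <- dim(arr) }
  if (length(d) != 3L) impt_abort("not a 3-D volume", "impt_error_not_3d")
  spacing <- abs(RNifti::pixdim(img)[1:3])
  origin <- RNifti::xform(img)[1:3, 4]
  dose_grid(arr, spacing = spacing, origin = as.double(origin))
}

## ---- DICOM RT Dose (read-only) ---------------------------------------------
## Minimal single-file parser for uncompressed little-endian RT Dose objects.
## Pixel values are unsigned 16/32-bit integers multiplied by DoseGridScaling.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_u16 <- function(raw, at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
dcm_u32 <- function(raw, at) sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))

# Parse a little-endian element stream; returns a named list keyed "gggg,eeee"
# with raw value fields. Explicit or implicit VR.
dcm_parse_elements <- function(raw, pos, end, explicit) {
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")
  while (pos + 7 <= end) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2)
    key <- sprintf("%04x,%04x", group, elem)
    if (explicit) {
      vr <- rawToChar(raw[pos + 4:5])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw, pos + 8); hdr <- 12L
      } else {
        len <- dcm_u16(raw, pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- dcm_u32(raw, pos + 4); hdr <- 8L
    }
    if (len == 4294967295) # undefined length (sequence) — skip unsupported
      impt_abort("undefined-length DICOM elements are not supported",
                 "impt_error_unsupported_transfer_syntax")
    val_at <- pos + hdr
    out[[key]] <- list(vr = vr, value = if (len > 0) raw[val_at:(val_at + len - 1)] else raw(0))
    pos <- val_at + len
  }
  out
}

dcm_str <- function(el) if (is.null(el)) NULL else
  sub("\\s+$", "", rawToChar(el$value[el$value != as.raw(0)]))
dcm_ds <- function(el) if (is.null(el)) NULL else as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_us <- function(el) if (is.null(el)) NULL else dcm_u16(el$value, 1)

read_dicom_rtdose <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  impt_check(length(raw) > 132 && rawToChar(raw[129:132]) == "DICM",
             "not a DICOM file (missing DICM magic)", "impt_error_bad_header")
  # file meta group is always explicit VR little endian
  meta_len_el <- dcm_parse_elements(raw, 133L, 144L, explicit = TRUE)
  meta_len <- dcm_u32(meta_len_el[["0002,0000"]]$value, 1)
  meta_end <- 144L + meta_len
  meta <- dcm_parse_elements(raw, 145L, meta_end, explicit = TRUE)
  ts <- dcm_str(meta[["0002,0010"]])
  ts <- trimws(ts %||% "")
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    impt_abort(sprintf("unsupported transfer syntax: %s", ts),
               "impt_error_unsupported_transfer_syntax")
  el <- dcm_parse_elements(raw, meta_end + 1L, length(raw),
                           explicit = ts == UID_EXPLICIT_LE)

  rows <- dcm_us(el[["0028,0010"]]); cols <- dcm_us(el[["0028,0011"]])
  nframes <- as.integer(dcm_str(el[["0028,0008"]]) %||% "1")
  bits <- dcm_us(el[["0028,0100"]]) %||% 16L
  scaling <- dcm_ds(el[["3004,000e"]])
  pixel_spacing <- dcm_ds(el[["0028,0030"]])  # (row spacing, column spacing)
  ipp <- dcm_ds(el[["0020,0032"]]) %||% c(0, 0, 0)
  gfov <- dcm_ds(el[["3004,000c"]])
  iop <- dcm_ds(el[["0020,0037"]])
  if (!is.null(iop) && any(abs(iop - c(1, 0, 0, 0, 1, 0)) > 1e-6))
    impt_abort("non-axial ImageOrientationPatient is not supported",
               "impt_error_unsupported_transfer_syntax")
  impt_check(!is.null(rows) && !is.null(cols) && !is.null(el[["7fe0,0010"]]),
             "missing required RT Dose elements", "impt_error_bad_header")
  if (is.na(nframes) || nframes < 2L && (is.null(gfov) || length(gfov) < 2L))
    impt_abort("not a 3-D volume", "impt_error_not_3d")
  impt_check(!is.null(scaling) && is.finite(scaling) && scaling > 0,
             "missing DoseGridScaling", "impt_error_bad_header")
  dz <- diff(gfov)
  impt_check(all(abs(dz - dz[1]) < 1e-6),
             "non-uniform GridFrameOffsetVector is not supported",
             "impt_error_bad_header")

  pix_raw <- el[["7fe0,0010"]]$value
  n <- as.integer(rows) * as.integer(cols) * nframes
  pix <- if (bits == 16L) {
    as.double(readBin(pix_raw, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "little"))
  } else if (bits == 32L) {
    v <- as.double(readBin(pix_raw, "integer", n = n, size = 4L, endian = "little"))
    ifelse(v < 0, v + 4294967296, v)
  } else impt_abort(sprintf("unsupported BitsAllocated: %d", bits),
                    "impt_error_bad_header")
  impt_check(length(pix) == n, "truncated PixelData", "impt_error_bad_header")

  # DICOM pixel order: frame-major, then row, then column (column fastest) ->
  # array dims (col = L/R, row = A/P, frame = S/I)
  arr <- array(pix * scaling, c(cols, rows, nframes))
  spacing <- c(pixel_spacing[2], pixel_spacing[1], abs(dz[1]))
  impt_check(all(is.finite(spacing)) && all(spacing > 0),
             "non-positive spacing in RT Dose", "impt_error_bad_spacing")
  dose_grid(arr, spacing = spacing, origin = ipp)
}
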