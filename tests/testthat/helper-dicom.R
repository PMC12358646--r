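# Writes a minimal synthetic DICOM RT Dose file (uncompressed little endian,
# explicit or implicit VR) byte-by-byte, independently of the package's
# parser, for reader tests.

dcm_raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_raw_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                    (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_pad <- function(value, pad = as.raw(0x20)) {
  if (length(value) %% 2 == 1) c(value, pad) else value
}

# One data element. For string VRs pass a character value.
dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  if (is.character(value))
    value <- dcm_pad(charToRaw(value), if (vr == "UI") as.raw(0) else as.raw(0x20))
  tag <- c(dcm_raw_u16(group), dcm_raw_u16(elem))
  if (!explicit) return(c(tag, dcm_raw_u32(length(value)), value))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_raw_u32(length(value)), value)
  else
    c(tag, charToRaw(vr), dcm_raw_u16(length(value)), value)
}

# Assemble an RT Dose file. `pixels` is an integer vector ordered
# column-fastest within frame (i.e. array dims c(cols, rows, frames)).
write_rtdose_dicom <- function(path, pixels, cols, rows, frames,
                               pixel_spacing = c(2, 1.5),  # (row, col) mm
                               ipp = c(0, 0, 0), frame_step = 2.5,
                               scaling = 0.001,
                               transfer_syntax = "1.2.840.10008.1.2.1") {
  explicit <- transfer_syntax == "1.2.840.10008.1.2.1"
  meta_body <- dcm_element(0x0002, 0x0010, "UI", transfer_syntax, explicit = TRUE)
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_raw_u32(length(meta_body)),
                        explicit = TRUE), meta_body)
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")
  pix_raw <- writeBin(as.integer(pixels), raw(), size = 2L, endian = "little")
  body <- c(
    dcm_element(0x0020, 0x0032, "DS", ds(ipp), explicit),
    dcm_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0)), explicit),
    dcm_element(0x0028, 0x0008, "IS", as.character(frames), explicit),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(rows), explicit),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(cols), explicit),
    dcm_element(0x0028, 0x0030, "DS", ds(pixel_spacing), explicit),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16), explicit),
    dcm_element(0x3004, 0x000c, "DS", ds((seq_len(frames) - 1) * frame_step), explicit),
    dcm_element(0x3004, 0x000e, "DS", format(scaling, scientific = FALSE), explicit),
    dcm_element(0x7fe0, 0x0010, "OW", pix_raw, explicit))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
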