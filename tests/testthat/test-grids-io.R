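test_that("dose_grid validates payload, spacing and dose values", {
  expect_error(dose_grid(matrix(1, 2, 2), c(1, 1, 1)), class = "impt_error_not_3d")
  expect_error(dose_grid(array(1, c(2, 2, 2)), c(1, 0, 1)),
               class = "impt_error_bad_spacing")
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)),
               class = "impt_error_invalid_dose")
  expect_error(dose_grid(array(NaN, c(2, 2, 2)), c(1, 1, 1)),
               class = "impt_error_invalid_dose")
  g <- dose_grid(array(1, c(4, 4, 4)), c(2.5, 2.5, 2.5))
  expect_equal(voxel_volume_cc(g), 0.015625)  # 2.5^3 / 1000
})

test_that("roi_mask enforces non-emptiness, rx and shape", {
  expect_error(roi_mask(array(FALSE, c(2, 2, 2)), "x", "oar", 60),
               class = "impt_error_empty_roi")
  expect_error(roi_mask(array(TRUE, c(2, 2, 2)), "x", "oar", 0),
               class = "impt_error_bad_rx")
  m <- roi_mask(array(c(1, 0), c(2, 2, 2)), "x", "oar", 60, spacing = c(2, 2, 2))
  expect_equal(sum(m$mask), 4)
  expect_equal(roi_volume_cc(m), 4 * 0.008)
})

test_that("volumes round-trip bitwise through NRRD and NIfTI", {
  for (fmt in c("nrrd", "nifti")) {
    for (seed in 1:3) {
      g <- random_grid(c(8, 8, 8), seed = seed, spacing = c(2.5, 1.25, 3),
                       origin = c(-10.5, 4.25, 0))
      path <- tempfile(fileext = if (fmt == "nrrd") ".nrrd" else ".nii.gz")
      write_volume(g, path)
      r <- read_volume(path)
      expect_identical(r$values, g$values)
      expect_equal(r$spacing, g$spacing, tolerance = 1e-9)
      expect_equal(r$origin, g$origin, tolerance = 1e-9)
      unlink(path)
    }
  }
})

test_that("zero grids and NaN grids are handled at the write boundary", {
  z <- dose_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
  p <- tempfile(fileext = ".nrrd")
  write_volume(z, p)
  expect_equal(max(read_volume(p)$values), 0)
  unlink(p)
  bad <- z; bad$values[1] <- NaN
  expect_error(write_volume(bad, p), class = "impt_error_invalid_dose")
  expect_false(file.exists(p))
})

test_that("read_volume raises distinct named errors", {
  expect_error(read_volume(tempfile(fileext = ".nrrd")),
               class = "impt_error_missing_file")
  # 2-D payload
  p <- tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 2", "sizes: 4 4",
               "encoding: ascii", ""), p)
  cat(rep(1, 16), file = p, append = TRUE)
  expect_error(read_volume(p), class = "impt_error_not_3d")
  unlink(p)
})

test_that("NRRD reader accepts ascii encoding and plain spacings", {
  p <- tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: float", "dimension: 3", "sizes: 2 2 2",
               "spacings: 1.5 2 2.5", "encoding: ascii", "",
               paste(1:8, collapse = " ")), p)
  g <- read_volume(p)
  expect_equal(g$values, array(as.double(1:8), c(2, 2, 2)))
  expect_equal(g$spacing, c(1.5, 2, 2.5))
  unlink(p)
})

test_that("axial slice extraction matches a per-voxel loop and checks bounds", {
  g <- random_grid(c(5, 4, 3), seed = 9)
  for (k in 1:3) {
    sl <- extract_axial_slice(g, k)
    ref <- matrix(0, 5, 4)
    for (i in 1:5) for (j in 1:4) ref[i, j] <- g$values[i, j, k]
    expect_identical(sl, ref)
  }
  expect_error(extract_axial_slice(g, 4), class = "impt_error_index_out_of_range")
  expect_error(extract_axial_slice(g, 0), class = "impt_error_index_out_of_range")
  u <- dose_grid(array(7, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(extract_axial_slice(u, 2) == 7))
})

test_that("DICOM RT Dose import scales pixels into Gy with correct geometry", {
  for (ts in c("1.2.840.10008.1.2.1", "1.2.840.10008.1.2")) {
    p <- tempfile(fileext = ".dcm")
    pix <- 0:23
    write_rtdose_dicom(p, pix, cols = 4, rows = 3, frames = 2,
                       pixel_spacing = c(2, 1.5), ipp = c(-10, -20, 5),
                       frame_step = 2.5, scaling = 0.0025, transfer_syntax = ts)
    g <- read_volume(p)
    expect_equal(g$values, array(pix * 0.0025, c(4, 3, 2)))
    expect_equal(g$spacing, c(1.5, 2, 2.5))  # (col, row, frame)
    expect_equal(g$origin, c(-10, -20, 5))
    unlink(p)
  }
})

test_that("unsupported DICOM transfer syntax raises its named error", {
  p <- tempfile(fileext = ".dcm")
  write_rtdose_dicom(p, 0:23, cols = 4, rows = 3, frames = 2,
                     transfer_syntax = "1.2.840.10008.1.2.4.70")
  expect_error(read_volume(p), class = "impt_error_unsupported_transfer_syntax")
  unlink(p)
})

test_that("read_mask builds an ROI from a nonzero label volume", {
  lab <- array(0, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1
  p <- tempfile(fileext = ".nii.gz")
  write_volume(dose_grid(lab, c(2, 2, 2)), p)
  m <- read_mask(p, "CTV", "target", rx = 60)
  expect_s3_class(m, "roi_mask")
  expect_equal(sum(m$mask), 8)
  unlink(p)
})
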