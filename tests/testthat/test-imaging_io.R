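test_that("mask decode/encode covers the gray dialect and round-trips", {
  all255 <- matrix(255, 4, 4)
  expect_true(all(mask_classes(decode_mask(all255, 3)) == 2L))
  all0 <- matrix(0, 4, 4)
  expect_true(all(mask_classes(decode_mask(all0, 2)) == 0L))
  # band membership: 140 is within +/-32 of 128
  expect_equal(mask_classes(decode_mask(matrix(140, 2, 2), 3))[1, 1], 1L)
  # out-of-band value reports value and coordinates
  bad <- matrix(0, 3, 3); bad[2, 3] <- 70
  expect_error(decode_mask(bad, 3), "70.*row 2, col 3")

  expect_equal(encode_mask(label_mask(matrix(2L, 2, 2), 3))[1, 1], 255L)
  expect_equal(encode_mask(label_mask(matrix(1L, 2, 2), 3))[1, 1], 128L)

  set.seed(11)
  for (nc in c(2L, 3L)) {
    for (i in 1:10) {
      m <- random_mask(nc)
      expect_identical(mask_classes(decode_mask(encode_mask(m), nc)),
                       mask_classes(m))
      expect_identical(mask_n_classes(decode_mask(encode_mask(m), nc)), nc)
    }
  }
})

test_that("PNG reading canonicalizes size, range, and grayscale channels", {
  tmp <- tempfile(fileext = ".png")
  # 8-bit constant-255 PNG at 448x448 -> all 1.0 at 224x224x3
  write_image_png(array(1, dim = c(448, 448, 1)), tmp)
  img <- read_image(tmp, "png")
  px <- unclass(img)
  expect_equal(dim(px), c(224L, 224L, 3L))
  expect_true(all(px == 1))

  # non-trivial grayscale content survives an 8-bit round trip
  ph <- generate_phantom(5, 0.6, noise_sd = 0)
  write_image_png(ph$image, tmp)
  back <- read_image(tmp, "png")
  expect_identical(back[, , 1], back[, , 2])
  expect_identical(back[, , 1], back[, , 3])
  expect_lt(max(abs(unclass(back) - unclass(ph$image))), 1.01 / 255)
  expect_true(min(back) >= 0 && max(back) <= 1)
  unlink(tmp)
})

test_that("mask PNG write/read round-trips for both class counts", {
  tmp <- tempfile(fileext = ".png")
  ph <- generate_phantom(2, 0.62, noise_sd = 0)
  write_mask_png(ph$mask, tmp)
  expect_identical(mask_classes(read_mask_png(tmp, 3)), mask_classes(ph$mask))
  m2 <- label_mask(matrix(as.integer(mask_classes(ph$mask) == 2L), 224, 224), 2)
  write_mask_png(m2, tmp)
  expect_identical(mask_classes(read_mask_png(tmp, 2)), mask_classes(m2))
  unlink(tmp)
})

test_that("DICOM writer/reader round-trips values, rescale, and frame checks", {
  tmp <- tempfile(fileext = ".dcm")
  set.seed(21)
  v <- matrix(sample(c(0L, 1000L), 32 * 32, replace = TRUE), 32, 32)
  cardioseg:::write_dicom(v, tmp, bits_allocated = 16)
  dcm <- read_dicom(tmp)
  expect_identical(dcm$pixels, v + 0)  # numeric comparison
  # min-max to [0,1] + nearest resize: only {0, 1} survive
  img <- read_image(tmp, "dicom", interpolation = "nearest")
  expect_setequal(unique(as.vector(unclass(img))), c(0, 1))
  expect_equal(dim(unclass(img)), c(224L, 224L, 3L))

  # rescale slope/intercept applied before normalization
  cardioseg:::write_dicom(v, tmp, bits_allocated = 16,
                          rescale_slope = 2, rescale_intercept = -100)
  expect_identical(read_dicom(tmp)$pixels, v * 2 - 100)

  # 8-bit path
  v8 <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  cardioseg:::write_dicom(v8, tmp, bits_allocated = 8)
  expect_identical(read_dicom(tmp)$pixels, v8 + 0)

  # multi-frame files are rejected with actionable advice
  cardioseg:::write_dicom(v, tmp, bits_allocated = 16, number_of_frames = 3)
  expect_error(read_dicom(tmp), "multi-frame.*single frame")
  unlink(tmp)
})

test_that("a pydicom-written file parses identically (independent writer)", {
  tmp <- tempfile(fileext = ".dcm")
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import numpy as np",
    "from pydicom.dataset import FileDataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, SecondaryCaptureImageStorage, generate_uid",
    "meta = FileMetaDataset()",
    "meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "meta.MediaStorageSOPClassUID = SecondaryCaptureImageStorage",
    "meta.MediaStorageSOPInstanceUID = generate_uid()",
    sprintf("ds = FileDataset(r'%s', {}, file_meta=meta, preamble=b'\\x00'*128)", tmp),
    "ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "ds.Rows = 8; ds.Columns = 6; ds.SamplesPerPixel = 1",
    "ds.PhotometricInterpretation = 'MONOCHROME2'",
    "ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "ds.PixelRepresentation = 0",
    "ds.RescaleSlope = '3'; ds.RescaleIntercept = '-10'",
    "arr = (np.arange(48, dtype=np.uint16) * 100).reshape(8, 6)",
    "ds.PixelData = arr.tobytes()",
    sprintf("ds.save_as(r'%s', enforce_file_format=True)", tmp)
  ), script)
  status <- system2(py, script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tmp))
  dcm <- read_dicom(tmp)
  expected <- t(matrix(seq(0, 47) * 100, nrow = 6)) * 3 - 10
  expect_equal(dcm$pixels, expected)
  unlink(c(tmp, script))
})

test_that("red overlay replaces exactly the masked pixels", {
  ph <- generate_phantom(9, 0.58, noise_sd = 0.02)
  zero <- label_mask(matrix(0L, 224, 224), 2)
  expect_identical(unclass(red_overlay(ph$image, zero)), unclass(ph$image))

  ones <- label_mask(matrix(1L, 224, 224), 2)
  all_red <- unclass(red_overlay(ph$image, ones))
  expect_true(all(all_red[, , 1] == 1) && all(all_red[, , 2] == 0) &&
                all(all_red[, , 3] == 0))

  set.seed(4)
  m <- matrix(0L, 224, 224)
  m[sample(length(m), 137)] <- 1L
  out <- unclass(red_overlay(ph$image, label_mask(m, 2)))
  differing <- apply(out != unclass(ph$image), c(1, 2), any)
  expect_equal(sum(differing), 137)

  expect_error(red_overlay(ph$image, label_mask(matrix(0L, 10, 10), 2)),
               "mismatch")
})

test_that("image224 and label_mask enforce their invariants", {
  expect_error(image224(array(0.5, dim = c(100, 100, 3))), "224x224x3")
  expect_error(image224(array(1.5, dim = c(224, 224, 3))), "\\[0, 1\\]")
  expect_error(label_mask(matrix(3L, 4, 4), 3), "values")
  expect_error(label_mask(matrix(0L, 4, 4), 5), "n_classes")
})
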