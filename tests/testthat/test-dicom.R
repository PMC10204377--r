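test_that("CT rescale identity and full write/read round trip", {
  px <- matrix(seq(-1000, 700, length.out = 40 * 30), 40, 30)
  px <- round(px)
  px[1, 1] <- 0  # stored 1024 with slope 1, intercept -1024
  img <- ct_image(px, spacing = c(0.8, 0.9), id = "rt-ct")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, f)
  back <- read_slice(f)
  expect_equal(back$pixels[1, 1], 0)
  expect_equal(back$pixels, px)   # integer HU survive exactly
  expect_identical(back$modality, "CT")
  expect_equal(back$pixel_spacing, c(0.8, 0.9))
  expect_identical(back$source_id, "rt-ct")
})

test_that("MR slice round-trips grid, spacing and metadata", {
  set.seed(4)
  px <- matrix(round(runif(320 * 260, 0, 1200)), 320, 260)
  img <- mr_image(px, spacing = c(1.40625, 1.40625), id = "rt-mr")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, f)
  back <- read_slice(f)
  expect_equal(dim(back$pixels), c(320, 260))
  expect_equal(back$pixel_spacing, c(1.40625, 1.40625))
  expect_identical(back$modality, "MR")
  expect_equal(back$pixels, px)
  expect_false(back$bias_corrected)
})

test_that("unsupported modality and missing pixel spacing are rejected", {
  px <- matrix(100L, 8, 8)
  pix_el <- adipoquant:::el_raw(0x7FE0, 0x0010, "OW",
    writeBin(as.integer(t(px)), raw(), size = 2, endian = "little"))
  base <- list(
    adipoquant:::el_us(0x0028, 0x0002, 1),
    adipoquant:::el_us(0x0028, 0x0010, 8),
    adipoquant:::el_us(0x0028, 0x0011, 8),
    adipoquant:::el_us(0x0028, 0x0100, 16),
    adipoquant:::el_us(0x0028, 0x0103, 0),
    pix_el)
  f1 <- withr::local_tempfile(fileext = ".dcm")
  adipoquant:::dcm_write_file(f1, adipoquant:::SOP_SC, c(
    list(adipoquant:::el_str(0x0008, 0x0060, "CS", "US"),
         adipoquant:::el_ds(0x0028, 0x0030, c(1, 1))), base))
  expect_error(read_slice(f1), "unsupported modality")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  adipoquant:::dcm_write_file(f2, adipoquant:::SOP_CT, c(
    list(adipoquant:::el_str(0x0008, 0x0060, "CS", "CT")), base))
  expect_error(read_slice(f2), "PixelSpacing")
})

test_that("secondary capture burns in contours over masks over grayscale", {
  ph <- generate_phantom(clean_spec(), "CT")
  q <- quantify_slice(ph$image)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_secondary_capture(q$image, q$contours, q$masks, f)
  arr <- read_secondary_capture(f)
  expect_equal(dim(arr), c(dim(ph$image$pixels), 3))

  # with empty masks, only contour pixels differ from the grayscale base
  empty <- fat_masks(matrix(FALSE, nrow(arr), ncol(arr)),
                     matrix(FALSE, nrow(arr), ncol(arr)))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_secondary_capture(q$image, q$contours, empty, f2)
  arr2 <- read_secondary_capture(f2)
  gray <- adipoquant:::display_gray(q$image)
  differs <- arr2[, , 1] != gray | arr2[, , 2] != gray | arr2[, , 3] != gray
  cpix <- rbind(adipoquant:::contour_pixels(q$contours$outer,
                                            nrow(gray), ncol(gray)),
                adipoquant:::contour_pixels(q$contours$inner,
                                            nrow(gray), ncol(gray)))
  on_contour <- matrix(FALSE, nrow(gray), ncol(gray))
  on_contour[cpix] <- TRUE
  expect_true(all(differs == on_contour))

  # a mask overlapping a contour pixel: the contour colour wins
  cover <- fat_masks(matrix(TRUE, nrow(gray), ncol(gray)),
                     matrix(FALSE, nrow(gray), ncol(gray)))
  f3 <- withr::local_tempfile(fileext = ".dcm")
  write_secondary_capture(q$image, q$contours, cover, f3)
  arr3 <- read_secondary_capture(f3)
  op <- adipoquant:::contour_pixels(q$contours$outer, nrow(gray), ncol(gray))
  idx <- op[, 1] + (op[, 2] - 1) * nrow(gray)
  expect_true(all(arr3[, , 1][idx] == 0 & arr3[, , 2][idx] == 255 &
                  arr3[, , 3][idx] == 0))
  expect_error(write_secondary_capture(q$image, q$contours,
    fat_masks(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), f3),
    "dimensions")
})

test_that("results CSV round trip preserves areas to 2 decimals", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(list(), f)
  expect_equal(nrow(utils::read.csv(f)), 0)

  r1 <- quant_result(736.333, 489.288, 242.119, 149.4, "CT", "s1")
  r2 <- quant_result(717.251, 474.209, 240.666, 129.81, "MR", "s2")
  write_results(list(r1, r2), f)
  txt <- readLines(f)
  expect_length(txt, 3)
  expect_match(txt[2], "149.4")   # fixed precision, no trailing zero padding
  back <- read_results(f)
  expect_equal(back[[1]]$vat_area_cm2, 149.4)
  expect_equal(back[[2]]$outer_area_cm2, round(717.251, 2))
  expect_identical(back[[2]]$modality, "MR")
})

test_that("result JSON mirrors the quant_result fields", {
  r <- quant_result(500, 300, 150, 80, "CT", "js1")
  f <- withr::local_tempfile(fileext = ".json")
  write_result_json(r, f, params_digest = "abcd1234")
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$outer_cm2, 500)
  expect_equal(obj$vat_cm2, 80)
  expect_identical(obj$params_digest, "abcd1234")
})

test_that("writer interoperates with an independent DICOM implementation", {
  # pydicom as the external oracle: our files must parse there with the
  # same calibrated values, and a pydicom-written file must parse here.
  px <- matrix(round(seq(-500, 300, length.out = 24 * 20)), 24, 20)
  img <- ct_image(px, spacing = c(1.25, 1.5), id = "xcheck")
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", f, "');",
    "import numpy as np;",
    "v = d.pixel_array.astype(float) * float(d.RescaleSlope)",
    " + float(d.RescaleIntercept);",
    "print(d.Modality, d.Rows, d.Columns,",
    " float(d.PixelSpacing[0]), float(d.PixelSpacing[1]),",
    " v[0,0], v[23,19], v.sum())"))), stdout = TRUE)
  parts <- strsplit(trimws(out[length(out)]), " +")[[1]]
  expect_identical(parts[1], "CT")
  expect_equal(as.numeric(parts[2:3]), c(24, 20))
  expect_equal(as.numeric(parts[4:5]), c(1.25, 1.5))
  expect_equal(as.numeric(parts[6]), px[1, 1])
  expect_equal(as.numeric(parts[7]), px[24, 20])
  expect_equal(as.numeric(parts[8]), sum(px))

  g <- withr::local_tempfile(fileext = ".dcm")
  status <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np, pydicom;",
    "from pydicom.dataset import Dataset, FileMetaDataset;",
    "from pydicom.uid import ExplicitVRLittleEndian;",
    "m = FileMetaDataset();",
    "m.TransferSyntaxUID = ExplicitVRLittleEndian;",
    "m.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.4';",
    "m.MediaStorageSOPInstanceUID = '2.25.123456';",
    "ds = Dataset(); ds.file_meta = m;",
    "ds.Modality = 'MR'; ds.Rows = 6; ds.Columns = 5;",
    "ds.PixelSpacing = ['1.5', '2.0'];",
    "ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = 'MONOCHROME2';",
    "ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15;",
    "ds.PixelRepresentation = 0;",
    "a = np.arange(30, dtype=np.uint16).reshape(6, 5);",
    "ds.PixelData = a.tobytes();",
    "ds.save_as('", g, "', enforce_file_format=True)"))))
  expect_equal(status, 0L)
  back <- read_slice(g)
  expect_identical(back$modality, "MR")
  expect_equal(back$pixel_spacing, c(1.5, 2.0))
  expect_equal(back$pixels, matrix(0:29, 6, 5, byrow = TRUE))
})
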