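# DICOM read/write, header rescaling, unified pixel grid.

test_that("header rescale maps raw values to output units", {
  # raw 1024 with slope 1, intercept -1024 encodes 0 HU
  p <- withr::local_tempfile(fileext = ".dcm")
  necromap:::.dcm_write(p, matrix(0, 2, 2), spacingMm = 0.5,
                        slope = 1, intercept = -1024)
  d <- necromap:::.dcm_read(p)
  expect_equal(d$values, matrix(1024, 2, 2))   # stored raw
  img <- readImage(p, modality = "CECT")
  expect_equal(gridValues(img), matrix(0, 2, 2))
})

test_that("reading at the native spacing returns values bit-for-bit", {
  p <- withr::local_tempfile(fileext = ".dcm")
  v <- matrix(sample(0:400, 36), 6, 6)
  writeImage(ImageGrid(v, 0.4, "CECT"), p, slope = 1, intercept = 0)
  img <- readImage(p, targetSpacingMm = 0.4)
  expect_identical(gridValues(img), v + 0)
  expect_identical(spacingMm(img), 0.4)
})

test_that("bilinear resampling reproduces corner nodes and interior bilinear values", {
  p <- withr::local_tempfile(fileext = ".dcm")
  v <- matrix(c(10, 30, 20, 60), 2, 2)        # [[10,20],[30,60]]
  writeImage(ImageGrid(v, 1, "CECT"), p, slope = 1, intercept = 0)
  img <- readImage(p, targetSpacingMm = 0.5)
  out <- gridValues(img)
  expect_equal(dim(out), c(4L, 4L))
  # closed-form bilinear at the query nodes u = 1 + (i-1)/3
  u <- 1 + (0:3) / 3
  expected <- outer(seq_along(u), seq_along(u), function(i, j) {
    fy <- u[i] - 1; fx <- u[j] - 1
    (1 - fy) * (1 - fx) * v[1, 1] + fy * (1 - fx) * v[2, 1] +
      (1 - fy) * fx * v[1, 2] + fy * fx * v[2, 2]
  })
  expect_equal(out, expected, tolerance = 1e-12)
  expect_equal(out[c(1, 4), c(1, 4)], v[c(1, 2), c(1, 2)])
})

test_that("masks binarize by > 0 and survive a write/read round trip", {
  p <- withr::local_tempfile(fileext = ".dcm")
  necromap:::.dcm_write(p, matrix(c(0, 255, 255, 0, 0, 255, 0, 0, 0), 3, 3),
                        spacingMm = 0.2, slope = 1, intercept = 0)
  m <- readMask(p)
  expect_true(all(maskValues(m) %in% c(0L, 1L)))
  expect_equal(sum(maskValues(m)), 3)

  rm0 <- ReferenceMask(matrix(c(0, 1, 1, 0, 1, 1, 0, 0, 0), 3, 3), 0.2,
                       markerXY = c(2, 1), landmarks = rbind(c(3, 3)))
  p2 <- withr::local_tempfile(fileext = ".dcm")
  writeMask(rm0, p2)
  back <- readMask(p2)
  expect_identical(maskValues(back), maskValues(rm0))
  expect_equal(markerXY(back), markerXY(rm0))
  expect_equal(landmarks(back), landmarks(rm0))
})

test_that("nearest-neighbour mask resampling keeps masks binary and areas stable", {
  sq <- matrix(0L, 8, 8); sq[3:6, 3:6] <- 1L     # 4x4 foreground square
  p <- withr::local_tempfile(fileext = ".dcm")
  writeMask(sq, p, spacingMm = 0.4)
  m <- readMask(p, targetSpacingMm = 0.4)
  expect_equal(sum(maskValues(m)), 16)
  m2 <- readMask(p, targetSpacingMm = 0.2)       # upsample 2x
  expect_true(all(maskValues(m2) %in% c(0L, 1L)))
  expect_equal(sum(maskValues(m2)) * 0.2^2, 16 * 0.4^2,
               tolerance = 0.3)                  # boundary ring at most
})

test_that("header errors are explicit: missing tags, multi-frame, bad rescale", {
  # hand-assembled file without PixelSpacing
  el <- necromap:::.dcm_element
  p <- withr::local_tempfile(fileext = ".dcm")
  pix <- writeBin(rep(0L, 4), raw(), size = 2, endian = "little")
  meta <- c(el(0x0002, 0x0010, "UI", necromap:::.DCM_TS_EXPLICIT))
  body <- c(el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
            el(0x7FE0, 0x0010, "OW", pix))
  con <- file(p, "wb")
  writeBin(c(raw(128), charToRaw("DICM"),
             el(0x0002, 0x0000, "UL", length(meta)), meta, body), con)
  close(con)
  expect_error(readImage(p), "PixelSpacing")

  # multi-frame flagged as unsupported
  p2 <- withr::local_tempfile(fileext = ".dcm")
  meta2 <- meta
  body2 <- c(el(0x0028, 0x0008, "IS", "2"),
             el(0x0028, 0x0030, "DS", "1\\1"), body)
  con <- file(p2, "wb")
  writeBin(c(raw(128), charToRaw("DICM"),
             el(0x0002, 0x0000, "UL", length(meta2)), meta2, body2), con)
  close(con)
  expect_error(readImage(p2), "multi-frame")

  # missing rescale on an image read
  p3 <- withr::local_tempfile(fileext = ".dcm")
  body3 <- c(el(0x0028, 0x0030, "DS", "1\\1"), body)
  con <- file(p3, "wb")
  writeBin(c(raw(128), charToRaw("DICM"),
             el(0x0002, 0x0000, "UL", length(meta)), meta, body3), con)
  close(con)
  expect_error(readImage(p3), "Rescale")
  expect_error(readMask(p3), "degenerate")       # mask path: no foreground
})

test_that("a reference DICOM toolkit reads our files identically", {
  p <- withr::local_tempfile(fileext = ".dcm")
  v <- matrix(c(-10, 250, 119, 300), 2, 2)
  writeImage(ImageGrid(v, 0.5, "CECT"), p, slope = 1, intercept = -1024)
  script <- paste(
    "import pydicom, sys",
    sprintf("d = pydicom.dcmread(r'%s')", p),
    "a = d.pixel_array * float(d.RescaleSlope) + float(d.RescaleIntercept)",
    "print(float(d.PixelSpacing[0]))",
    "print(' '.join(str(float(x)) for x in a.ravel()))",
    sep = "\n")
  out <- system2("python", "-", input = script, stdout = TRUE)
  expect_equal(as.numeric(out[1]), 0.5)
  # pydicom returns row-major order
  expect_equal(as.numeric(strsplit(out[2], " ")[[1]]),
               as.vector(t(v)))
})

test_that("writeOutputs enforces the canonical schema and refuses collisions", {
  d <- withr::local_tempdir()
  rec <- data.frame(tpr = 0.9, tp = 90, ablation_id = "a1", fdr = 0.25,
                    fp = 30, fn = 10, adr = 2.25, modality = "CECT",
                    threshold = 200)
  paths <- writeOutputs(tables = list(confusion = rec), outDir = d)
  got <- readLines(paths[1], n = 1)
  expect_equal(got,
    "\"ablation_id\",\"modality\",\"threshold\",\"tp\",\"fp\",\"fn\",\"tpr\",\"fdr\",\"adr\"")
  expect_error(writeOutputs(tables = list(confusion = rec), outDir = d),
               "refusing to overwrite")

  # empty record list -> header only
  p2 <- writeOutputs(tables = list(empty = rec[0, ]), outDir = d)
  expect_length(readLines(p2[1]), 1L)

  # two masks -> two DICOM files in the manifest
  msk <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  p3 <- writeOutputs(masks = list(m1 = msk, m2 = msk), outDir = d,
                     spacingMm = 0.2)
  expect_length(p3, 2L)
  expect_true(all(file.exists(p3)))
})
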