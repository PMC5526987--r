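test_that("grayscale TIFF round-trips pixel-exactly", {
  rf <- stdPhantomField(rnRadius = 15, haloScale = 20, noiseSd = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  writeField(rf$field, path)
  back <- loadField(path)
  expect_identical(pixels(back), pixels(rf$field))
  expect_equal(sourceId(back), basename(path))
})

test_that("an all-black field loads as all zeros with the right dimensions", {
  f <- intensityField(matrix(0L, 10, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  writeField(f, path)
  back <- loadField(path)
  expect_equal(dim(back), c(10L, 10L))
  expect_true(all(pixels(back) == 0L))
})

test_that("RGB input collapses under the chosen channel policy", {
  arr <- array(0, c(4, 5, 3))
  arr[1, 1, ] <- c(10, 200, 30) / 255
  arr[2, 3, ] <- c(120, 60, 90) / 255
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  expect_equal(pixels(loadField(path, "max"))[1, 1], 200L)
  expect_equal(pixels(loadField(path, "red"))[2, 3], 120L)
  expect_equal(pixels(loadField(path, "green"))[1, 1], 200L)
  expect_equal(pixels(loadField(path, "blue"))[2, 3], 90L)
  lum <- pixels(loadField(path, "luminance"))[1, 1]
  expect_equal(lum, round(0.299 * 10 + 0.587 * 200 + 0.114 * 30))
})

test_that("deep bit depths and unreadable files are rejected explicitly", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(20), 4, 5), path, bits.per.sample = 16L)
  expect_error(loadField(path), "bit depth")
  expect_error(loadField(file.path(tempdir(), "nope.tif")), "nope.tif")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(loadField(bad), "cannot read")
})

test_that("overlays draw one closed contour pair per measured halo", {
  specs <- list(
    phantomSpec(c(150, 150), rnRadius = 15, peak = 255, haloScale = 20),
    phantomSpec(c(150, 420), rnRadius = 20, peak = 240, haloScale = 25),
    phantomSpec(c(380, 285), rnRadius = 12, peak = 230, haloScale = 18))
  rf <- renderField(specs, 570, 530, seed = 4)
  res <- measureField(rf$field, testConfig("x55/15"))
  stem <- file.path(withr::local_tempdir(), "ov")
  paths <- writeOverlay(rf$field, res, stem)
  expect_true(all(file.exists(paths)))
  countContours <- function(p, channel) {
    img <- png::readPNG(p)
    marked <- img[, , channel] == 1 & img[, , setdiff(1:3, channel)[1]] == 0
    length(bruteComponentsOracle(marked))
  }
  expect_equal(countContours(paths[["rn"]], 1), 3L)
  expect_equal(countContours(paths[["outer"]], 2), 3L)
})

test_that("an empty field gives overlays identical to the grayscale input", {
  f <- intensityField(matrix(12L, 30, 30))
  res <- measureField(f, testConfig())
  stem <- file.path(withr::local_tempdir(), "blank")
  paths <- writeOverlay(f, res, stem)
  img <- png::readPNG(paths[["rn"]])
  expect_equal(img[, , 1], img[, , 2])
  expect_equal(img[, , 1], img[, , 3])
  expect_equal(round(img[, , 1] * 255), matrix(12, 30, 30))
})

test_that("the measurement CSV has one row per object and empty cells on failure", {
  hdr <- c("source_id", "object_index", "frame_time_s", "local_max",
           "rn_area_px", "outer_area_px", "rn_radius_px", "outer_radius_px",
           "halo_radius_px", "status", "class")
  path <- withr::local_tempfile(fileext = ".csv")
  # empty result list: header only
  writeMeasurementsCSV(list(), path)
  expect_identical(readLines(path), paste(hdr, collapse = ","))
  # one measured cell: one data row
  rf <- stdPhantomField(rnRadius = 15, haloScale = 20, seed = 2)
  res <- measureField(rf$field, testConfig())
  writeMeasurementsCSV(res, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), hdr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$status, "measured")
  # a class-II phantom: rn cells empty, status recorded
  rf2 <- renderClassPhantom("II", seed = 3)
  res2 <- measureField(rf2$field, testConfig())
  writeMeasurementsCSV(list(res, res2), path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$status[2], "rn_fail")
  expect_true(is.na(tab$rn_area_px[2]))
  raw <- readLines(path)[3]
  expect_match(raw, ",,")  # genuinely empty cells, not "NA"
})

test_that("CSV row count equals detected objects summed over inputs", {
  specs <- list(
    phantomSpec(c(150, 150), rnRadius = 15, peak = 255, haloScale = 20),
    phantomSpec(c(150, 420), rnRadius = 20, peak = 240, haloScale = 25))
  rf <- renderField(specs, 570, 300, seed = 10)
  res1 <- measureField(rf$field, testConfig())
  rf2 <- stdPhantomField(seed = 11)
  res2 <- measureField(rf2$field, testConfig())
  path <- withr::local_tempfile(fileext = ".csv")
  writeMeasurementsCSV(list(res1, res2), path)
  expect_equal(nrow(utils::read.csv(path)), 3L)
})
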