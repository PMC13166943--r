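test_that("multi-page TIFF round-trips by role, independent of file order", {
  set.seed(101)
  mats <- lapply(1:4, function(i) matrix(sample(0:65535, 64 * 64, TRUE),
                                         64, 64))
  p <- withr::local_tempfile(fileext = ".tif")
  writeTIFFGray(mats, p, bitDepth = 16L)
  # roles deliberately not in page order
  map <- channelMap(phospho_met = 4, nuclear_stain = 1, total_met = 3,
                    membrane_marker = 2)
  s <- readMultichannelImage(p, map, pixelSizeUm = 0.5)
  expect_setequal(stackRoles(s), c("nuclear_stain", "membrane_marker",
                                   "total_met", "phospho_met"))
  expect_identical(dim(s), c(64L, 64L))
  for (i in 1:4)
    expect_identical(getChannel(s, names(map)[match(i, map)]), mats[[i]] + 0)
  expect_equal(pixelSize(s), 0.5)
})

test_that("out-of-range channel index and bad inputs error", {
  p <- withr::local_tempfile(fileext = ".tif")
  writeTIFFGray(lapply(1:4, function(i) matrix(i, 8, 8)), p)
  expect_error(
    readMultichannelImage(p, channelMap(nuclear_stain = 7),
                          pixelSizeUm = 0.5),
    "channel index out of range")
  expect_error(
    readMultichannelImage(p, channelMap(nuclear_stain = 1),
                          pixelSizeUm = -1),
    "pixelSizeUm")
  expect_error(readMultichannelImage("no/such/file.tif",
                                     channelMap(nuclear_stain = 1),
                                     pixelSizeUm = 0.5),
               "not found")
  expect_error(channelMap(nuclear_stain = 1, nuclear_stain = 2), "unique")
  expect_error(channelMap(not_a_role = 1), "unknown channel role")
})

test_that("per-channel files are accepted via named paths", {
  d <- withr::local_tempdir()
  m1 <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  m2 <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  writeTIFFGray(m1, file.path(d, "dapi.tif"), 8L)
  writeTIFFGray(m2, file.path(d, "met.tif"), 8L)
  s <- readMultichannelImage(
    c(nuclear_stain = file.path(d, "dapi.tif"),
      total_met = file.path(d, "met.tif")), pixelSizeUm = 0.25)
  expect_identical(getChannel(s, "nuclear_stain"), m1 + 0)
  expect_identical(getChannel(s, "total_met"), m2 + 0)
  # mismatched shapes across per-role files are rejected
  writeTIFFGray(matrix(0L, 16, 16), file.path(d, "small.tif"), 8L)
  expect_error(readMultichannelImage(
    c(nuclear_stain = file.path(d, "dapi.tif"),
      total_met = file.path(d, "small.tif")), pixelSizeUm = 0.25),
    "mismatched")
})

test_that("write-then-read of a generated scene is the identity on pixels", {
  sc <- generateScene(sceneSpec(seed = 5))
  p <- withr::local_tempfile(fileext = ".tif")
  map <- writeChannelStack(sc$stack, p)
  back <- readMultichannelImage(p, map, pixelSizeUm = pixelSize(sc$stack))
  for (role in stackRoles(sc$stack))
    expect_identical(getChannel(back, role), getChannel(sc$stack, role))
  # and for 8-bit data
  sc8 <- generateScene(sceneSpec(seed = 5, bitDepth = 8L,
                                 backgroundMean = 10, signalMean = 200,
                                 noiseSd = 3))
  p8 <- withr::local_tempfile(fileext = ".tif")
  map8 <- writeChannelStack(sc8$stack, p8)
  back8 <- readMultichannelImage(p8, map8, pixelSizeUm = 0.5)
  for (role in stackRoles(sc8$stack))
    expect_identical(getChannel(back8, role), getChannel(sc8$stack, role))
})

test_that("quant table writes a header plus one row per record, NA not 0", {
  sc <- generateScene(sceneSpec(seed = 3))
  masks <- segmentCompartments(sc$stack)
  rec <- quantifyField(sc$stack, masks, fixedThresholds(),
                       rois = list(
                         list(roi_id = "a", rows = c(1, 64), cols = c(1, 64)),
                         list(roi_id = "b", rows = c(1, 64), cols = c(65, 128)),
                         list(roi_id = "c", rows = c(65, 128), cols = c(1, 128))))
  p <- withr::local_tempfile(fileext = ".csv")
  writeQuantTable(rec, p)
  lines <- readLines(p)
  expect_length(lines, 4L)  # header + 3 rows
  # a record with an empty membrane denominator must render NA, never 0
  empty <- matrix(FALSE, 4, 4)
  st <- testStack(nuclear_stain = matrix(0, 4, 4),
                  membrane_marker = matrix(0, 4, 4),
                  total_met = matrix(0, 4, 4),
                  phospho_met = matrix(0, 4, 4))
  cm <- new("CompartmentMasks", nuclear = empty, membrane = empty,
            tissue = empty, nucleusCount = 0L, fieldId = "x")
  r0 <- quantifyField(st, cm, fixedThresholds())
  expect_true(is.na(r0$pct_map_total_met))
  p0 <- withr::local_tempfile(fileext = ".csv")
  writeQuantTable(r0, p0)
  parsed <- readQuantTable(p0)
  expect_true(is.na(parsed$pct_map_total_met))
  expect_match(r0$qc_notes, "empty membrane mask")
  expect_error(writeQuantTable(data.frame(), tempfile()), "non-empty")
})

test_that("a 50-record table round-trips to full precision", {
  set.seed(77)
  rec <- data.frame(field_id = sprintf("f%02d", 1:50), roi_id = "full",
                    specimen_id = "s", group = "g",
                    nucleus_count = sample(0:40, 50, TRUE),
                    pct_map_total_met = runif(50) * 100,
                    area_per_cell_um2_total_met = rexp(50) * 30,
                    phospho_total_ratio = runif(50),
                    qc_notes = "", stringsAsFactors = FALSE)
  rec$pct_map_total_met[4] <- NA
  p <- withr::local_tempfile(fileext = ".csv")
  writeQuantTable(rec, p)
  back <- readQuantTable(p)
  expect_equal(back, rec)
  # determinism: identical inputs give byte-identical files
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeQuantTable(rec, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})
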