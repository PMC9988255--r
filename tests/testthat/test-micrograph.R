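test_that("micrograph constructor enforces its invariants", {
  arr <- array(0, dim = c(4, 4, 3),
               dimnames = list(NULL, NULL, c("red", "green", "blue")))
  m <- micrograph(arr, pixel_size_um = 0.5)
  expect_s3_class(m, "micrograph")
  expect_identical(dim(m$pixels), c(4L, 4L, 3L))

  expect_error(micrograph(array(0, c(4, 4, 2)), 0.5), "H x W x 3")
  expect_error(micrograph(arr, -1), "positive")
  arr2 <- arr; arr2[1, 1, 1] <- NA
  expect_error(micrograph(arr2, 0.5), "finite")
  arr3 <- arr; arr3[1, 1, 1] <- 300
  expect_error(micrograph(arr3, 0.5), "255")
  bad <- arr; dimnames(bad) <- list(NULL, NULL, c("r", "g", "b"))
  expect_error(micrograph(bad, 0.5), "red/green/blue")
})

test_that("8-bit TIFF write/read round trip preserves intensities exactly", {
  set.seed(11)
  arr <- array(sample(0:255, 10 * 8 * 3, replace = TRUE), dim = c(10, 8, 3),
               dimnames = list(NULL, NULL, c("red", "green", "blue")))
  m <- micrograph(arr, pixel_size_um = 300 / 1320, subject_id = "r1")
  path <- file.path(tempdir(), "roundtrip.tif")
  write_micrograph(m, path)
  m2 <- read_micrograph(path, list(pixel_size_um = 300 / 1320, subject = "r1"))
  expect_equal(m2$pixels[, , "red"], unname(arr[, , "red"]), tolerance = 0)
  expect_equal(m2$pixels, arr, ignore_attr = TRUE, tolerance = 0)
  expect_equal(m2$pixel_size_um, 300 / 1320)
})

test_that("16-bit images are rescaled onto the 0-255 convention", {
  arr16 <- array(c(rep(0, 6), rep(1, 6)), dim = c(2, 2, 3))  # writeTIFF scale
  path <- file.path(tempdir(), "deep.tif")
  tiff::writeTIFF(arr16, path, bits.per.sample = 16L)
  m <- read_micrograph(path, list(pixel_size_um = 1))
  expect_equal(max(m$pixels), 255)
  expect_equal(min(m$pixels), 0)
})

test_that("all-zero image maps to all-zero intensities", {
  path <- file.path(tempdir(), "zero.tif")
  tiff::writeTIFF(array(0, c(2, 2, 3)), path, bits.per.sample = 8L)
  m <- read_micrograph(path, list(pixel_size_um = 300 / 1320))
  expect_true(all(m$pixels == 0))
  expect_equal(m$pixel_size_um, 300 / 1320, tolerance = 1e-12)
})

test_that("unreadable files and bad metadata raise informative errors", {
  expect_error(read_micrograph("/nonexistent/file.tif"), "not found")
  path <- file.path(tempdir(), "gray.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), path, bits.per.sample = 8L)
  expect_error(read_micrograph(path, list(pixel_size_um = 1)), "channel")
  path2 <- file.path(tempdir(), "ok.tif")
  tiff::writeTIFF(array(0.5, c(2, 2, 3)), path2, bits.per.sample = 8L)
  expect_error(read_micrograph(path2, list(pixel_size_um = -2)), "pixel_size_um")
})

test_that("manifest loading validates schema, keys and files", {
  dir <- file.path(tempdir(), "man1")
  dir.create(dir, showWarnings = FALSE)
  for (f in c("a.tif", "b.tif", "c.tif"))
    tiff::writeTIFF(array(0.5, c(2, 2, 3)), file.path(dir, f), bits.per.sample = 8L)
  man_df <- data.frame(path = c("a.tif", "b.tif", "c.tif"),
                       subject = c("s1", "s1", "s2"),
                       region = c("VO", "LO", "VO"),
                       hemisphere = "left", ap_mm = 3.7,
                       pixel_size_um = 300 / 1320, group = "CTL")
  mp <- file.path(dir, "manifest.csv")
  write.csv(man_df, mp, row.names = FALSE)
  man <- load_manifest(mp)
  expect_s3_class(man, "fiber_manifest")
  expect_equal(nrow(man), 3L)
  expect_identical(man$subject, c("s1", "s1", "s2"))  # order preserved
  expect_identical(load_manifest(mp)$subject, man$subject)  # idempotent

  dup <- man_df; dup$subject <- "s1"; dup$region <- "VO"
  write.csv(dup, mp, row.names = FALSE)
  expect_error(load_manifest(mp), "duplicate")

  write.csv(man_df[, -2], mp, row.names = FALSE)
  expect_error(load_manifest(mp), "missing required column")

  write.csv(man_df[0, ], mp, row.names = FALSE)
  expect_warning(empty <- load_manifest(mp), "no records")
  expect_equal(nrow(empty), 0L)
})
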