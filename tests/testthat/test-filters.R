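test_that("channel combination computes the weighted sum, unclipped", {
  w <- c(blue = 1, red = -0.25, green = -0.25)
  expect_equal(combine_channels(flat_micrograph(2, 2, c(255, 255, 255)), w)[1, 1], 127.5)
  expect_equal(combine_channels(flat_micrograph(2, 2, c(0, 0, 0)), w)[1, 1], 0)
  expect_equal(combine_channels(flat_micrograph(2, 2, c(0, 0, 255)), w)[1, 1], 255)
  # signed output: a red-only pixel combines to a negative value
  expect_equal(combine_channels(flat_micrograph(1, 1, c(200, 0, 0)), w)[1, 1], -50)
  expect_error(combine_channels(random_micrograph(4, 4), c(blue = 1, red = 1)),
               "missing channel")
})

test_that("median filter removes impulses and preserves constants", {
  expect_equal(median_denoise(matrix(7, 12, 12), 3), matrix(7, 12, 12),
               ignore_attr = TRUE)
  z <- matrix(0, 15, 15); z[8, 8] <- 100
  out <- median_denoise(z, 3)
  expect_equal(out[8, 8], 0)
  expect_true(all(out == 0))
  expect_error(median_denoise(matrix(0, 4, 4), 5), "smaller")
  expect_error(median_denoise(matrix(0, 4, 4), 0), ">= 1")
})

test_that("median filter matches the sliding-disk oracle on random planes", {
  set.seed(101)
  for (rep in 1:4) {
    x <- matrix(runif(16 * 16, -20, 120), 16, 16)
    expect_equal(median_denoise(x, 3), oracle_median_disk(x, 3),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # non-square plane and radius 1
  x <- matrix(rnorm(12 * 20), 12, 20)
  expect_equal(median_denoise(x, 1), oracle_median_disk(x, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("high-pass is zero on constants and cancels uniform offsets", {
  expect_true(all(abs(highpass(matrix(42, 20, 20), 3)) < 1e-10))
  set.seed(7)
  x <- matrix(runif(24 * 24, 0, 200), 24, 24)
  h1 <- highpass(x, 4)
  h2 <- highpass(x + 57.3, 4)
  expect_equal(h1, h2, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(highpass(x, -1), "positive")
})

test_that("high-pass of a dark line matches the dense-convolution oracle", {
  x <- matrix(150, 32, 32)
  x[, 16] <- 20                       # 1-px-wide dark vertical line
  hp <- highpass(x, 3, polarity = "stain_dark")
  ref <- -(x - oracle_gaussian(x, 3))
  expect_equal(hp, ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(max(hp[, 16]), 0)         # stain-dark polarity: line is positive
  # stain_bright polarity flips the sign
  expect_equal(highpass(x, 3, "stain_bright"), -hp,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("thresholding uses >= and honors the stain mask", {
  hp <- matrix(0, 3, 3)
  hp[1, 1] <- 10; hp[2, 2] <- 11; hp[3, 3] <- 12
  det <- threshold_fibers(hp, level = 11)
  expect_identical(sum(det), 2L)
  expect_false(det[1, 1]); expect_true(det[2, 2]); expect_true(det[3, 3])
  expect_identical(sum(threshold_fibers(matrix(0, 4, 4), level = 11)), 0L)
  # exhaustive count with exclusions
  set.seed(13)
  hp2 <- matrix(runif(100, 0, 22), 10, 10)
  stain <- matrix(FALSE, 10, 10); stain[1:5, 1] <- TRUE
  expected <- sum(hp2 >= 11 & !stain)
  expect_identical(sum(threshold_fibers(hp2, stain, 11)), expected)
  expect_error(threshold_fibers(hp2, matrix(FALSE, 2, 2), 11), "dimensions")
  # negative values never detected
  expect_false(any(threshold_fibers(matrix(-50, 4, 4), level = 11)))
})

test_that("volume fraction is the detected-pixel proportion", {
  expect_equal(volume_fraction(matrix(TRUE, 5, 5)), 1)
  expect_equal(volume_fraction(matrix(FALSE, 5, 5)), 0)
  m <- matrix(FALSE, 10, 10); m[1:25] <- TRUE
  expect_equal(volume_fraction(m), 0.25)
  expect_error(volume_fraction(matrix(logical(0), 0, 0)), "zero-size")
})

test_that("focus QC computes the dual-scale ratio and pass flag", {
  r <- focus_qc(0.04, 0.04, 0.5)
  expect_equal(r$qc_ratio, 1); expect_true(r$qc_pass)
  r2 <- focus_qc(0.01, 0.05, 0.5)
  expect_equal(r2$qc_ratio, 0.2); expect_false(r2$qc_pass)
  expect_warning(r3 <- focus_qc(0, 0, 0.5), "undefined")
  expect_true(is.na(r3$qc_ratio)); expect_false(r3$qc_pass)
  expect_error(focus_qc(0.1, 0.1, 0), "cutoff")
  expect_error(focus_qc(0.1, 0.1, 1.5), "cutoff")
  expect_error(focus_qc(1.2, 0.1, 0.5), "\\[0, 1\\]")
})
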