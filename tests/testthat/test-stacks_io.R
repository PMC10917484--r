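test_that("write/read round trip is bit-faithful at each precision", {
  set.seed(101)
  a <- array(runif(60) * 5 - 1, c(4, 5, 3))
  s32 <- image_stack(a, "binary32")
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s32, f)
  r <- read_stack(f)
  expect_identical(r$data, s32$data)
  expect_identical(r$precision, "binary32")

  s64 <- image_stack(a, "binary64")
  f2 <- withr::local_tempfile(fileext = ".rawstack")
  write_stack(s64, f2)
  r2 <- read_stack(f2)
  expect_identical(r2$data, s64$data)
  expect_identical(r2$precision, "binary64")

  # a stored binary64 value is the binary64 nearest to its decimal source
  s03 <- image_stack(array(0.3, c(1, 1, 1)), "binary64")
  f3 <- withr::local_tempfile(fileext = ".rawstack")
  write_stack(s03, f3)
  expect_identical(read_stack(f3)$data[1, 1, 1], 0.3)
})

test_that("float32 TIFF pages are readable by the independent libtiff reader", {
  set.seed(7)
  a <- array(rnorm(24), c(2, 4, 3))  # values outside [0, 1] included
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(a, "binary32"), f)
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_length(pages, 3L)
  expect_identical(pages[[2]], f32(a)[, , 2])
})

test_that("single-page TIFF reads as a one-frame stack", {
  s <- image_stack(array(runif(12), c(3, 4, 1)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, f)
  expect_identical(dim(read_stack(f)), c(3L, 4L, 1L))
})

test_that("a full-size synthetic stack keeps its 128 x 256 x 180 shape on disk", {
  s <- image_stack(array(0, c(128, 256, 180)), "binary32")
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, f)
  expect_identical(dim(read_stack(f)), c(128L, 256L, 180L))
})

test_that("integer TIFF pages are promoted to float keeping raw values", {
  m <- matrix(0:19, 4, 5) / 255
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f, bits.per.sample = 8L)
  r <- read_stack(f)
  expect_identical(r$data[, , 1], matrix(as.double(0:19), 4, 5))
  expect_identical(r$precision, "binary32")
})

test_that("read errors are distinct named conditions", {
  expect_error(read_stack(file.path(tempdir(), "does-not-exist.tif")),
               class = "hd_error_missing_file")

  rgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(36), c(3, 4, 3)), rgb)
  expect_error(read_stack(rgb), class = "hd_error_not_grayscale")

  empty <- withr::local_tempfile(fileext = ".tif")
  con <- file(empty, "wb")
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")  # no IFDs: zero pages
  close(con)
  expect_error(read_stack(empty), class = "hd_error_empty_stack")

  junk <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff at all", junk)
  expect_error(read_stack(junk), class = "hd_error_bad_format")
})

test_that("write errors are distinct named conditions", {
  s64 <- image_stack(array(runif(8), c(2, 2, 2)), "binary64")
  f <- withr::local_tempfile(fileext = ".tif")
  expect_error(write_stack(s64, f, precision = "binary32"),
               class = "hd_error_precision_narrowing")
  expect_silent(write_stack(s64, f, precision = "binary32", allow_narrowing = TRUE))
  expect_error(write_stack(s64, f),  # binary64 payload cannot go into TIFF
               class = "hd_error_unsupported_precision")
  expect_error(write_stack(s64, file.path(tempdir(), "no-such-dir", "x.rawstack")),
               class = "hd_error_unwritable")
  expect_error(write_stack(s64, withr::local_tempfile(fileext = ".png")),
               class = "hd_error_bad_format")
})

test_that("as_precision rounds to nearest, is idempotent, fixes integers", {
  ints <- image_stack(array(as.double(0:10), c(11, 1, 1)), "binary64")
  expect_identical(as_precision(ints, "binary32")$data, ints$data)

  s <- image_stack(array(0.3, c(1, 1, 1)), "binary64")
  s32 <- as_precision(s, "binary32")
  expect_identical(s32$data[1, 1, 1], 0.300000011920928955078125)
  expect_identical(s$data[1, 1, 1], 0.3)  # input unchanged

  set.seed(3)
  r <- image_stack(array(rnorm(40), c(4, 5, 2)), "binary64")
  once <- as_precision(r, "binary32")
  expect_identical(as_precision(once, "binary32")$data, once$data)
})

test_that("stack construction rejects invalid data", {
  expect_error(image_stack(array(c(1, NA), c(2, 1, 1))), class = "hd_error_bad_stack")
  expect_error(image_stack(array(c(1, Inf), c(2, 1, 1))), class = "hd_error_bad_stack")
  expect_error(image_stack("nope"), class = "hd_error_bad_stack")
})
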