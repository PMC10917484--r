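test_that("quality reproduces the hand-computed single-frame example", {
  ref <- array(c(1, 1), c(1, 2, 1))
  tst <- array(c(1, 0), c(1, 2, 1))
  q <- quality(ref, tst)$per_frame
  expect_equal(q$rmse, sqrt(0.5), tolerance = 1e-12)
  expect_equal(q$mae, 0.5, tolerance = 1e-12)
  expect_equal(q$snr, 10 * log10(2), tolerance = 1e-12)    # ~3.0103 dB
  expect_equal(q$psnr, 10 * log10(1 / 0.5), tolerance = 1e-12)
})

test_that("identical stacks give zero error and infinite SNR/PSNR", {
  set.seed(41)
  a <- array(runif(60), c(5, 4, 3))
  q <- quality(a, a)
  expect_identical(q$per_frame$rmse, rep(0, 3))
  expect_identical(q$per_frame$mae, rep(0, 3))
  expect_true(all(is.infinite(q$per_frame$snr)))
  expect_true(all(is.infinite(q$per_frame$psnr)))

  # serialized with string sentinels, not non-finite numbers
  f <- withr::local_tempfile(fileext = ".json")
  write_quality_json(q, f)
  parsed <- jsonlite::read_json(f)
  expect_identical(parsed$per_frame[[1]]$snr, "+Inf")
})

test_that("scaling both inputs leaves SNR fixed and scales RMSE/MAE", {
  set.seed(42)
  r <- array(runif(80) + 0.5, c(4, 5, 4))
  t <- r + array(rnorm(80, 0, 0.05), c(4, 5, 4))
  q1 <- quality(r, t)
  q3 <- quality(3 * r, 3 * t)
  expect_equal(q3$per_frame$snr, q1$per_frame$snr, tolerance = 1e-10)
  expect_equal(q3$per_frame$rmse, 3 * q1$per_frame$rmse, tolerance = 1e-10)
  expect_equal(q3$per_frame$mae, 3 * q1$per_frame$mae, tolerance = 1e-10)

  # RMSE/MAE are symmetric under swapping ref and test; SNR need not be
  qs <- quality(t, r)
  expect_equal(qs$per_frame$rmse, q1$per_frame$rmse, tolerance = 1e-12)
  expect_equal(qs$per_frame$mae, q1$per_frame$mae, tolerance = 1e-12)
})

test_that("quality rejects shape mismatches and flags all-zero reference frames", {
  expect_error(quality(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               class = "hd_error_shape_mismatch")
  ref <- array(0, c(2, 2, 1))
  tst <- array(1, c(2, 2, 1))
  q <- quality(ref, tst)
  expect_true(is.na(q$per_frame$snr))   # SNR undefined for an all-zero frame
  expect_false(is.na(q$per_frame$rmse))
})

test_that("byte_compare is an exact equivalence oracle", {
  set.seed(43)
  a <- image_stack(array(runif(48), c(4, 4, 3)), "binary32")
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(a, f1)
  write_stack(a, f2)
  rep_same <- byte_compare(f1, f2)
  expect_false(rep_same$structural_difference)
  expect_identical(rep_same$n_differing_bytes, 0L)

  expect_true(byte_compare(as.raw(1:10), as.raw(1:9))$structural_difference)
})

test_that("one-ulp binary32 differences land on a 4-byte stride", {
  # values with clean low mantissa bits, then bumped by exactly one ulp
  x <- f32(0.5 + (1:64) * 2^-10)
  y <- f32(x * (1 + 2^-23))
  expect_false(identical(x, y))
  ra <- writeBin(as.vector(x), raw(), size = 4L)
  rb <- writeBin(as.vector(y), raw(), size = 4L)
  rep <- byte_compare(ra, rb)
  expect_gt(rep$n_differing_bytes, 0L)
  # every differing byte is the low-order byte of its 4-byte word
  expect_true(all(rep$differing_offsets %% 4L == 0L))
  expect_identical(unname(rep$word_phase_histogram[["0"]]),
                   rep$n_differing_bytes)
})

test_that("line profiles cover the center row and address frame 50", {
  cst <- image_stack(array(2.5, c(8, 6, 4)))
  p <- line_profile(cst, 2)
  expect_identical(p$row, 4L)          # ceiling(8 / 2)
  expect_identical(p$values, rep(2.5, 6))  # exactly representable at binary32
  expect_length(p$positions, 6L)

  set.seed(44)
  big <- image_stack(array(runif(8 * 6 * 180), c(8, 6, 180)), "binary64")
  p50 <- line_profile(big, 50)
  expect_identical(p50$frame, 50L)
  expect_identical(p50$values, big$data[4, , 50])

  expect_error(line_profile(cst, 9), class = "hd_error_out_of_range")
  expect_error(line_profile(cst, 1, row = 0), class = "hd_error_out_of_range")

  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p50, f)
  csv <- utils::read.csv(f)
  expect_identical(nrow(csv), 6L)
  expect_equal(csv$value, p50$values, tolerance = 0)
})

test_that("float_repr prints exact expansions and round-trips", {
  expect_identical(float_repr("0.3", "binary32"),
                   "0.300000011920928955078125")
  expect_identical(float_repr("0.3", "binary64"),
                   "0.299999999999999988897769753748434595763683319091796875")
  expect_identical(float_repr("0.5", "binary32"), "0.5")
  expect_identical(float_repr("0.5", "binary64"), "0.5")
  expect_identical(float_repr("7", "binary32"), "7")
  expect_identical(float_repr("-0.25", "binary64"), "-0.25")
  expect_identical(float_repr("0", "binary64"), "0")

  set.seed(45)
  for (v in c(rnorm(10), 10^runif(5, -8, 8), 1e300, 5e-324)) {
    s64 <- float_repr(sprintf("%.17g", v), "binary64")
    expect_identical(as.numeric(s64), v)
  }
  for (v in f32(runif(10) * 100 - 50)) {
    s32 <- float_repr(sprintf("%.9g", v), "binary32")
    expect_identical(f32(as.numeric(s32)), v)
  }

  expect_error(float_repr("not-a-number", "binary64"),
               class = "hd_error_unparseable")
})
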