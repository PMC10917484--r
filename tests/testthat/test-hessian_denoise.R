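test_that("shrink matches its closed form and is nonexpansive", {
  expect_identical(shrink(0, 5), 0)
  expect_identical(shrink(c(-1, 2), 0), c(-1, 2))
  expect_identical(shrink(3, 1), 2)
  expect_identical(shrink(-3, 1), -2)
  expect_error(shrink(1, -0.1), class = "hd_error_bad_param")

  set.seed(20)
  v <- rnorm(200)
  for (t in c(0, 0.3, 2)) {
    expect_true(all(abs(shrink(v, t)) <= abs(v)))
  }

  ctr <- call_counters()
  shrink(v, 1, counters = ctr)
  expect_identical(ctr$shrink_executions, 1L)
})

test_that("a constant stack is a fixed point of the iteration", {
  f <- array(3.7, c(6, 5, 4))
  params <- denoise_params(mu = 2, iterations = 1)
  sp <- build_spectrum(dim(f), params$sigma, params$weights)
  step <- iterate_once(f, f, new_split_state(dim(f)), sp, params)
  expect_lt(max(abs(step$u - f)), 1e-13)

  res <- denoise_reference(image_stack(f, "binary64"),
                           denoise_params(mu = 2, iterations = 10))
  expect_lt(max(abs(res$stack$data - f)), 1e-12)
})

test_that("one iteration matches the straight-line transcription oracle bit-exactly", {
  set.seed(21)
  shape <- c(4, 4, 4)
  f <- array(runif(prod(shape)), shape)
  params <- denoise_params(mu = 1.5, sigma = 0.9, iterations = 1,
                           precision = "binary64")
  sp <- build_spectrum(shape, params$sigma, params$weights)

  got <- iterate_once(f, f, new_split_state(shape), sp, params)
  want <- oracle_iterate_once(f, f, new_split_state(shape), sp$values,
                              params$mu, params$lambda, params$weights)
  expect_identical(got$u, want$u)
  for (d in DIRS) {
    expect_identical(got$state$d[[d]], want$state$d[[d]])
    expect_identical(got$state$b[[d]], want$state$b[[d]])
  }

  # a second chained iteration still agrees bit-exactly
  got2 <- iterate_once(got$u, f, got$state, sp, params)
  want2 <- oracle_iterate_once(want$u, f, want$state, sp$values,
                               params$mu, params$lambda, params$weights)
  expect_identical(got2$u, want2$u)
})

test_that("counters advance by 24 difference calls and 6 shrinks per iteration", {
  set.seed(22)
  f <- array(runif(64), c(4, 4, 4))
  params <- denoise_params(mu = 1, iterations = 1)
  sp <- build_spectrum(dim(f), params$sigma, params$weights)
  ctr <- call_counters()
  st <- iterate_once(f, f, new_split_state(dim(f)), sp, params, counters = ctr)
  expect_identical(ctr$forward_calls + ctr$backward_calls, 24L)
  expect_identical(ctr$forward_calls, 12L)
  expect_identical(ctr$shrink_executions, 6L)
  expect_identical(ctr$iterations_completed, 1L)

  iterate_once(st$u, f, st$state, sp, params, counters = ctr)
  expect_identical(ctr$forward_calls + ctr$backward_calls, 48L)
  expect_identical(ctr$shrink_executions, 12L)
})

test_that("the spatial mean of the input is preserved through the run", {
  ph <- small_phantom(shape = c(12, 10, 8), seed = 23)
  res <- denoise_reference(ph$noisy, denoise_params(mu = 2, iterations = 15))
  expect_lt(abs(mean(res$stack$data) - mean(ph$noisy$data)),
            1e-10 * abs(mean(ph$noisy$data)))
})

test_that("optimized binary64 CPU output is bit-identical to the reference", {
  for (seed in c(31, 32)) {
    ph <- small_phantom(shape = c(10, 9, 7), seed = seed)
    params <- denoise_params(mu = 2, iterations = 12, precision = "binary64",
                             cache_dir = withr::local_tempdir())
    ref <- denoise_reference(ph$noisy, params)
    opt <- denoise_optimized(ph$noisy, params)
    expect_identical(opt$stack$data, ref$stack$data)
  }
})

test_that("binary32 output differs bytewise but stays within tolerance", {
  ph <- small_phantom(shape = c(10, 9, 7), seed = 33)
  dir <- withr::local_tempdir()
  ref <- denoise_reference(ph$noisy,
                           denoise_params(mu = 2, iterations = 12,
                                          precision = "binary64"))
  opt <- denoise_optimized(ph$noisy,
                           denoise_params(mu = 2, iterations = 12,
                                          precision = "binary32", cache_dir = dir))
  expect_false(identical(f32(ref$stack$data), opt$stack$data))
  expect_lt(max(abs(opt$stack$data - ref$stack$data)) / max(abs(ref$stack$data)),
            1e-4)
})

test_that("cpu_parallel reproduces cpu_serial bit-exactly across repeated runs", {
  ph <- small_phantom(shape = c(10, 8, 6), seed = 34)
  dir <- withr::local_tempdir()
  serial <- denoise_optimized(ph$noisy,
                              denoise_params(mu = 2, iterations = 8,
                                             precision = "binary64",
                                             backend = "cpu_serial", cache_dir = dir))
  for (run in 1:3) {
    par <- denoise_optimized(ph$noisy,
                             denoise_params(mu = 2, iterations = 8,
                                            precision = "binary64",
                                            backend = "cpu_parallel", cache_dir = dir))
    expect_identical(par$stack$data, serial$stack$data)
  }
})

test_that("output approaches the input as mu grows", {
  ph <- small_phantom(shape = c(12, 12, 8), seed = 35)
  dists <- vapply(c(0.5, 2, 10, 40), function(mu) {
    res <- denoise_optimized(ph$noisy,
                             denoise_params(mu = mu, iterations = 10,
                                            cache_dir = withr::local_tempdir()))
    rmse_of(res$stack, as_precision(ph$noisy, "binary32"))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("device backend requires a driver and honors the transfer contract", {
  old <- clear_device_backend()
  withr::defer(if (!is.null(old)) register_device_backend(old))

  ph <- small_phantom(shape = c(8, 8, 4), seed = 36)
  params_dev <- denoise_params(mu = 2, iterations = 5, precision = "binary64",
                               backend = "device")
  expect_error(denoise_optimized(ph$noisy, params_dev),
               class = "hd_error_device_unavailable")

  params_fb <- denoise_params(mu = 2, iterations = 5, precision = "binary64",
                              backend = "device", fallback = TRUE)
  expect_warning(fb <- denoise_optimized(ph$noisy, params_fb),
                 class = "hd_warning_device_fallback")
  cpu <- denoise_optimized(ph$noisy,
                           denoise_params(mu = 2, iterations = 5,
                                          precision = "binary64"))
  expect_identical(fb$stack$data, cpu$stack$data)

  register_device_backend(simulated_device_backend())
  withr::defer(clear_device_backend())
  dev <- denoise_optimized(ph$noisy, params_dev)
  expect_identical(dev$stack$data, cpu$stack$data)
  expect_identical(dev$diagnostics$device$uploads, 1L)
  expect_identical(dev$diagnostics$device$gathers, 1L)
})

test_that("iterations and shapes are validated", {
  expect_error(denoise_params(mu = 0), class = "hd_error_bad_param")
  expect_error(denoise_params(iterations = 0), class = "hd_error_bad_param")
  ph <- small_phantom(shape = c(6, 6, 4), seed = 37)
  sp <- build_spectrum(c(5, 5, 5))
  expect_error(iterate_once(ph$noisy$data, ph$noisy$data,
                            new_split_state(dim(ph$noisy$data)), sp,
                            denoise_params()),
               class = "hd_error_shape_mismatch")
})

test_that("diagnostics record objective decrease and update magnitude", {
  ph <- small_phantom(shape = c(8, 8, 6), seed = 38)
  res <- denoise_optimized(ph$noisy,
                           denoise_params(mu = 2, iterations = 10,
                                          diagnostics = TRUE,
                                          cache_dir = withr::local_tempdir()))
  expect_length(res$diagnostics$objective, 10L)
  expect_length(res$diagnostics$max_delta_u, 10L)
  expect_true(all(is.finite(res$diagnostics$objective)))
  # the objective settles: the last value is below the first
  expect_lt(res$diagnostics$objective[10], res$diagnostics$objective[1])
})
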