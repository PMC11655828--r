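test_that("the EMA readiness potential matches its closed form", {
  fs <- 100
  # zero drive -> identically zero RP
  z <- extract_rp(rep(0, 500), smoothing = 100, fs = fs)
  expect_true(all(z$amplitude == 0))
  expect_true(is.na(z$threshold_crossing))
  # step drive -> exponential approach to the asymptote -tau_eff * step
  step <- rep(1, 2000)
  rp <- extract_rp(step, smoothing = 200, fs = fs)
  tt <- (seq_along(step) - 1) / fs * 1000
  alpha <- (1000 / fs) / 200
  expected <- -(1 - (1 - alpha)^(seq_along(step)))
  expect_equal(rp$amplitude, expected, tolerance = 1e-9)
  expect_gt(abs(rp$amplitude[2000]), 0.99)
  expect_error(extract_rp(step, smoothing = 0, fs = fs), "smoothing")
})

test_that("RP magnitude is non-decreasing under non-decreasing drive", {
  set.seed(4)
  for (k in 1:10) {
    drive <- cumsum(runif(400))            # non-decreasing
    rp <- extract_rp(drive, smoothing = 150, fs = 100)
    expect_true(all(diff(abs(rp$amplitude)) >= -1e-12))
  }
  # crossing is reported exactly when |amplitude| exceeds the threshold
  rp <- extract_rp(rep(1, 300), smoothing = 100, fs = 100,
                   awareness_threshold = 0.5)
  expect_false(is.na(rp$threshold_crossing))
  expect_gte(min(abs(rp$amplitude[rp$time >= rp$threshold_crossing])), 0.5)
})

test_that("a protocol run is reproducible given the seed", {
  res1 <- cached("proto_small", {
    brain <- build_brain(seed = 1)
    suppressWarnings(run_protocol(brain, small_protocol_config(seed = 1)))
  })
  brain <- build_brain(seed = 1)
  res2 <- suppressWarnings(run_protocol(brain, small_protocol_config(seed = 1)))
  expect_identical(res1$iterations, res2$iterations)
  expect_identical(res1$rp$amplitude, res2$rp$amplitude)
  expect_equal(res1$mode, "deliberate")
  expect_equal(nrow(res1$iterations), 2L)
})

test_that("uncorrelated external input routes through the arbitrary pathway", {
  brain <- build_brain(seed = 1)
  res <- suppressWarnings(
    run_protocol(brain, small_protocol_config(seed = 1, ext_phase = pi / 2)))
  expect_equal(res$mode, "arbitrary")
  expect_equal(nrow(res$iterations), 1L)   # single feed-forward pass
  expect_true(all(res$multipliers == 1))
})

test_that("a stimulus-free run gives a flat RP and stable metrics", {
  brain <- build_brain(seed = 1)
  res <- suppressWarnings(
    run_protocol(brain, small_protocol_config(seed = 1, acc_drive = 0,
                                              ba9_ctx_drive = 0)))
  expect_null(res$gate)
  # flat RP: tiny amplitude, no crossing
  expect_lt(max(abs(res$rp$amplitude)), res$config$awareness_threshold)
  expect_true(is.na(res$rp$threshold_crossing))
  # metrics approximately constant across iterations
  expect_lt(abs(diff(res$iterations$entropy)), 0.2)
})

test_that("iteration epochs must cover the slowest membrane time constant", {
  brain <- build_brain(seed = 1)
  expect_error(run_protocol(brain, protocol_config(iteration_duration = 500)),
               "slowest membrane")
})
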