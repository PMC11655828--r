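test_that("the BA9 gate resolves correlation against the threshold", {
  t <- seq(0, 1, by = 1e-3)
  s <- sin(2 * pi * 6 * t)
  g <- ba9_gate(s, s, threshold = 0.3)
  expect_equal(g$correlation, 1)
  expect_equal(g$pathway, "a_disinhibit")
  g2 <- ba9_gate(s, -s, threshold = 0.3)
  expect_equal(g2$correlation, -1)
  expect_equal(g2$pathway, "b_suppress")
})

test_that("independent noise falls within the analytic null and suppresses", {
  # null SD of the Pearson correlation is 1/sqrt(n)
  set.seed(5)
  n <- 1e4
  a <- rnorm(n)
  b <- rnorm(n)
  g <- ba9_gate(a, b, threshold = 0.3)
  expect_lt(abs(g$correlation), 5 / sqrt(n))
  expect_equal(g$pathway, "b_suppress")
})

test_that("the gate boundary resolves to disinhibition and errors are explicit", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  g <- ba9_gate(x, x, threshold = 1)   # correlation exactly 1 == threshold
  expect_equal(g$pathway, "a_disinhibit")
  expect_error(ba9_gate(rep(1, 100), rnorm(100)), "zero-variance")
  expect_equal(classify_pathway(g), "deliberate")
  g2 <- ba9_gate(rnorm(100), rnorm(100), threshold = 2)
  expect_equal(classify_pathway(g2), "arbitrary")
})

test_that("the carrier concentrates power in the theta band", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  acc <- avol_ts(list(ACC = sin(2 * pi * 6 * t) + 0.3 * rnorm(length(t))),
                 fs = fs)
  st <- carrier_signal(acc, targets = 1:10)
  carr <- attr(st, "carrier")
  sg <- spectrogram(ts_channel(carr), fs = fs, window = 1000)
  in_band <- sg$f >= 4 & sg$f < 8
  expect_gt(sum(rowMeans(sg$power)[in_band]) / sum(rowMeans(sg$power)), 0.8)
  expect_equal(st$label, "internal")
})

test_that("broadband input is confined to the carrier band (> 20 dB stopband)", {
  fs <- 1000
  set.seed(2)
  acc <- avol_ts(list(ACC = rnorm(4000)), fs = fs)
  carr <- ts_channel(attr(carrier_signal(acc, targets = 1), "carrier"))
  sp <- Mod(fft(carr))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  pass <- mean(sp[f >= 4.5 & f <= 7.5])
  stop_band <- mean(sp[f >= 20 & f <= 80])
  expect_gt(10 * log10(pass / stop_band), 20)
})

test_that("a silent ACC yields a near-zero carrier and short windows error", {
  fs <- 1000
  acc0 <- avol_ts(list(ACC = rep(0.5, 3000)), fs = fs)
  st <- carrier_signal(acc0, targets = 1:3)
  expect_lt(max(abs(ts_channel(attr(st, "carrier")))), 1e-8)
  short <- avol_ts(list(ACC = rnorm(300)), fs = fs)  # 0.3 s < 3 cycles at 4 Hz
  expect_error(carrier_signal(short, targets = 1), "3 cycles")
})

test_that("salience competition orders coupled above uncoupled assemblies", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)[-1]
  carrier <- sin(2 * pi * 6 * t)
  coupled <- (1 + sin(2 * pi * 6 * t)) / 2 * sin(2 * pi * 20 * t) +
    0.05 * rnorm(length(t))
  uncoupled <- 0.5 * sin(2 * pi * 24 * t) + 0.05 * rnorm(length(t))
  m <- salience_compete(list(a = coupled, b = uncoupled), carrier, fs = fs)
  expect_gt(m["a"], m["b"])
  expect_gt(m["a"], 1)
  expect_lt(m["b"], 1)
})

test_that("identical assemblies and silent carriers modulate nothing", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)[-1]
  x <- sin(2 * pi * 20 * t) + 0.02 * sin(2 * pi * 6 * t)
  m <- salience_compete(list(a = x, b = x), sin(2 * pi * 6 * t), fs = fs)
  expect_equal(unname(m["a"]), unname(m["b"]))
  m0 <- salience_compete(list(a = x, b = 2 * x), rep(0, length(t)), fs = fs)
  expect_true(all(m0 == 1))
  expect_error(salience_compete(list(), sin(t), fs = fs), "empty")
})

test_that("zero expectancy silences the BA46 feedforward drive", {
  brain <- cached("brain1", build_brain(seed = 1))
  fs <- 1000
  acc <- avol_ts(list(ACC = sin(2 * pi * 6 * seq(0, 2, by = 1 / fs))),
                 fs = fs)
  pair <- acc_ba46_feedforward(acc, brain$areas$BA46,
                               expectancy = c(0, 0, 0, 0))
  tt <- seq(0, 2000, by = 1)
  expect_true(all(pair$exc$waveform(tt) == 0))
  expect_null(pair$ff)
  # non-zero expectancy drives both layers
  pair2 <- acc_ba46_feedforward(acc, brain$areas$BA46,
                                expectancy = c(1, 0.2, 0.2, 0.2),
                                scale = 0.5)
  expect_s3_class(pair2$ff, "stimulus_spec")
  expect_true(isTRUE(attr(pair2$ff, "ff_ok")))
  expect_gt(max(pair2$exc$waveform(seq(0, 1000))), 0)
})

test_that("oscillation frequency is non-decreasing with feedforward drive", {
  # frequency-vs-drive sweep on one fast area: increasing simultaneous
  # E / FF-inhibitory drive must not lower the dominant frequency
  st <- build_area(default_brain_config()$areas$BA46, seed = 2)
  freqs <- vapply(c(0.05, 0.4, 0.8, 1.3, 1.8), function(drive) {
    stims <- list(stimulus_spec(st$idx_e, drive))
    ff <- stimulus_spec(st$idx_ff, drive * 0.1)
    attr(ff, "ff_ok") <- TRUE
    out <- simulate(st, seed = 3, duration = 1500, dt = 0.1,
                    stimuli = c(stims, list(ff)))
    x <- ts_channel(out, "E")
    dominant_frequency(x[-seq_len(500)], fs = out$fs, range = c(3, 100))
  }, 0)
  expect_true(all(diff(freqs) > -3))       # non-decreasing up to resolution
  expect_gt(freqs[5], freqs[1])            # and clearly rising overall
  expect_gt(freqs[5], 30)                  # into gamma when strongly driven
})
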