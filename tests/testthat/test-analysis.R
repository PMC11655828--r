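test_that("embedding obeys the point-count formula", {
  x <- rnorm(100)
  tr <- takens_embed(x, m = 2, lag = 1)
  expect_equal(nrow(tr$points), 99L)
  for (case in list(c(500, 3, 7), c(1000, 5, 12), c(256, 4, 3))) {
    tr <- takens_embed(rnorm(case[1]), m = case[2], lag = case[3])
    expect_equal(nrow(tr$points), case[1] - (case[2] - 1) * case[3])
  }
  expect_error(takens_embed(rnorm(30), m = 5, lag = 8), "too short")
})

test_that("auto lag agrees with a brute-force mutual-information oracle", {
  fs <- 1000
  x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / fs))   # 100 samples per period
  lag <- select_lag_ami(x)
  # brute-force oracle: discretised mutual information over all lags,
  # first local minimum
  mi_at <- function(lag, bins = 16) {
    n <- length(x) - lag
    bx <- cut(x, bins, labels = FALSE)
    tab <- table(bx[1:n], bx[(lag + 1):(lag + n)]) / n
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  }
  mi <- vapply(1:60, mi_at, 0)
  oracle_lag <- which(diff(mi) > 0)[1]
  expect_true(abs(lag - oracle_lag) <= 2)
  # a usable delay: at least one sample, below half a period, and the
  # resulting embedding still resolves the limit cycle
  expect_gte(lag, 1)
  expect_lt(lag, 50)
  d2 <- correlation_dimension(takens_embed(x, m = "auto", lag = lag,
                                           fs = fs))
  expect_equal(d2$value, 1.0, tolerance = 0.1)
})

test_that("constant signals are rejected for embedding", {
  expect_error(select_lag_ami(rep(1, 500)), "constant")
})

test_that("correlation dimension recovers known attractor dimensions", {
  s <- generate_fixture(fixture_spec("sine", n = 2000, fs = 1000,
                                     params = list(freq = 10)))
  tr <- takens_embed(ts_channel(s), fs = 1000)
  d2 <- correlation_dimension(tr)
  expect_equal(d2$value, 1.0, tolerance = 0.1)

  lo <- cached("lorenz20k",
               generate_fixture(fixture_spec("lorenz", n = 20000, fs = 100)))
  trl <- takens_embed(ts_channel(lo), m = 3, lag = "auto", fs = 100)
  d2l <- correlation_dimension(trl)
  expect_true(d2l$reliable)
  expect_equal(d2l$value, 2.05, tolerance = 0.15)
})

test_that("independent pair-count oracle agrees with the GP implementation", {
  # O(N^2) R reference at fixed radii, slope by least squares
  lo <- cached("lorenz20k",
               generate_fixture(fixture_spec("lorenz", n = 20000, fs = 100)))
  x <- ts_channel(lo)[seq(1, 20000, by = 4)]   # thin for the R oracle
  tr <- takens_embed(x, m = 3, lag = 5, fs = 25)
  pts <- tr$points
  N <- nrow(pts)
  theiler <- 15L
  ext <- max(apply(pts, 2, function(c) diff(range(c))))
  radii <- exp(seq(log(0.02 * ext), log(0.12 * ext), length.out = 8))
  counts <- numeric(8)
  total <- 0
  idx <- seq(1, N, by = 3)
  for (a in idx) {
    js <- (a + theiler + 1):N
    if (length(js) < 1 || js[1] > N) next
    d <- pmax(abs(pts[js, 1] - pts[a, 1]), abs(pts[js, 2] - pts[a, 2]))
    d <- pmax(d, abs(pts[js, 3] - pts[a, 3]))
    total <- total + length(js)
    counts <- counts + vapply(radii, function(r) sum(d <= r), 0)
  }
  oracle_slope <- unname(coef(lm(log(counts / total) ~ log(radii)))[2])
  cs <- avol:::gp_corr_sum_cpp(pts, radii, theiler)
  impl_slope <- unname(coef(lm(log(cs) ~ log(radii)))[2])
  expect_equal(impl_slope, oracle_slope, tolerance = 0.15)
})

test_that("D2 is invariant to amplitude scaling and time reversal", {
  s <- generate_fixture(fixture_spec("lorenz", n = 6000, fs = 100))
  x <- ts_channel(s)
  d2 <- function(z) correlation_dimension(takens_embed(z, m = 3, lag = 17,
                                                       fs = 100))$value
  base <- d2(x)
  expect_equal(d2(3.7 * x), base, tolerance = 0.05)
  expect_equal(d2(rev(x)), base, tolerance = 0.25)
})

test_that("noise-like signals raise the unreliable flag", {
  wn <- generate_fixture(fixture_spec("white_noise", n = 4000, fs = 1000))
  tr <- takens_embed(ts_channel(wn), m = 5, lag = 1, fs = 1000)
  expect_false(correlation_dimension(tr)$reliable)
  expect_false(lyapunov_largest(tr)$reliable)
})

test_that("the largest Lyapunov exponent separates periodic from chaotic", {
  s <- generate_fixture(fixture_spec("sine", n = 2000, fs = 1000,
                                     params = list(freq = 10)))
  tr <- takens_embed(ts_channel(s), fs = 1000)
  expect_lte(lyapunov_largest(tr)$value, 0.05)

  lo <- cached("lorenz20k",
               generate_fixture(fixture_spec("lorenz", n = 20000, fs = 100)))
  trl <- takens_embed(ts_channel(lo), m = 3, lag = "auto", fs = 100)
  ly <- lyapunov_largest(trl, k_max = 300)
  # Benettin two-trajectory oracle on the known ODE gives ~0.9 per unit time
  expect_equal(ly$value, 0.9, tolerance = 0.2)
  expect_true(ly$reliable)
})

test_that("Benettin renormalisation oracle confirms the Lorenz exponent", {
  f <- function(y) c(10 * (y[2] - y[1]),
                     y[1] * (28 - y[3]) - y[2],
                     y[1] * y[2] - 8 / 3 * y[3])
  rk4 <- function(y, h) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  h <- 0.005
  y <- c(1, 1, 1)
  for (k in 1:2000) y <- rk4(y, h)      # transient
  d0 <- 1e-7
  z <- y + c(d0, 0, 0)
  acc <- 0
  n_ren <- 600
  for (k in seq_len(n_ren)) {
    for (s in 1:20) { y <- rk4(y, h); z <- rk4(z, h) }
    d1 <- sqrt(sum((z - y)^2))
    acc <- acc + log(d1 / d0)
    z <- y + (z - y) * d0 / d1
  }
  lam <- acc / (n_ren * 20 * h)
  expect_equal(lam, 0.906, tolerance = 0.1)
})

test_that("sample entropy behaves as an ordering of disorder", {
  expect_equal(sample_entropy(rep(2, 600))$value, 0)
  set.seed(1)
  tt <- seq(0, 1, length.out = 600)
  wins <- 0
  for (k in 1:100) {
    wn <- rnorm(600)
    sn <- sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
    if (sample_entropy(wn)$value > sample_entropy(sn)$value) wins <- wins + 1
  }
  expect_equal(wins, 100)
})

test_that("sample entropy matches a direct R reference on a short series", {
  set.seed(3)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  ref_count <- function(m) {
    n <- length(x) - m
    tpl <- sapply(seq_len(n), function(i) x[i:(i + m - 1)])
    cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (max(abs(tpl[, i] - tpl[, j])) <= r) cnt <- cnt + 1
    cnt
  }
  ref <- -log(ref_count(3) / ref_count(2))
  expect_equal(sample_entropy(x, m = 2, r = 0.2)$value, ref,
               tolerance = 1e-10)
})

test_that("the spectrogram localises tones and silence", {
  fs <- 1000
  x <- sin(2 * pi * 40 * seq(0, 2, by = 1 / fs))
  sg <- spectrogram(x, fs = fs, window = 500)
  expect_lt(abs(sg$f[which.max(rowMeans(sg$power))] - 40), 2.1)
  expect_equal(sg$dominant_band, "gamma")
  z <- spectrogram(rep(0, 2000), fs = fs, window = 500)
  expect_true(all(z$power == 0))
  expect_error(spectrogram(rnorm(100), fs = fs, window = 500), "window")
})

test_that("PAC detects constructed coupling and respects the null", {
  pg <- generate_fixture(fixture_spec("theta_modulated_gamma", n = 10000,
                                      fs = 1000))
  pr <- pac_mvl(ts_channel(pg), fs = 1000, n_surrogates = 200)
  expect_gt(pr$mvl, 0.5)
  expect_lt(pr$surrogate_p, 0.01)
  wn <- generate_fixture(fixture_spec("white_noise", n = 6000, fs = 1000,
                                      seed = 2))
  nul <- pac_mvl(ts_channel(wn), fs = 1000, n_surrogates = 200, seed = 2)
  expect_gt(nul$surrogate_p, 0.05)
  expect_true(nul$mvl >= 0 && nul$mvl <= 1)
  expect_error(pac_mvl(ts_channel(wn), fs = 1000, phase_band = c(4, 40),
                       amp_band = c(30, 80)), "overlap")
})

test_that("the amplitude-weighted mean vector length matches its definition", {
  # direct construction: envelope ((1+cos p)/2)^2 modulating a fast carrier;
  # analytic weighted MVL = (1/4) / (3/8) = 2/3
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)[-1]
  ph <- 2 * pi * 6 * t
  env <- ((1 + cos(ph)) / 2)^2
  mvl_def <- Mod(mean(env * exp(1i * ph))) / mean(env)
  expect_equal(mvl_def, 2 / 3, tolerance = 1e-3)
  x <- cos(ph) + env * cos(2 * pi * 40 * t)
  pr <- pac_mvl(x, fs = fs, n_surrogates = 50)
  expect_equal(pr$mvl, mvl_def, tolerance = 0.15)
})

test_that("mvl lies in [0,1] for arbitrary inputs", {
  set.seed(8)
  for (k in 1:5) {
    x <- rnorm(3000) + sin(2 * pi * runif(1, 5, 7) * seq_len(3000) / 1000)
    pr <- pac_mvl(x, fs = 1000, n_surrogates = 20, seed = k)
    expect_true(pr$mvl >= 0 && pr$mvl <= 1)
    expect_true(all(pr$surrogates >= 0 & pr$surrogates <= 1))
  }
})
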