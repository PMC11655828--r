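#' Delay embedding of a scalar time series
#'
#' Reconstructs the phase space of a scalar signal by Takens delay embedding:
#' point `k` is `(x[k], x[k + lag], ..., x[k + (m-1) lag])`, giving
#' `N - (m - 1) * lag` points for input length `N`. With `lag = "auto"` the
#' delay is the first local minimum of the average mutual information; with
#' `m = "auto"` the dimension is the smallest for which the false-nearest-
#' neighbour fraction drops below `fnn_tol`.
#'
#' @param x Numeric vector or [avol_ts()] (first channel used).
#' @param m Embedding dimension (integer) or `"auto"`.
#' @param lag Embedding delay in samples (integer) or `"auto"`.
#' @param fs Sampling rate, Hz (taken from `x` when it is an `avol_ts`).
#' @param fnn_tol Threshold on the FNN fraction for automatic `m`.
#' @param m_max Largest dimension tried in automatic selection.
#' @return An object of class `embedded_trajectory`: list with `points`
#'   (matrix, one row per point), `m`, `lag`, `fs`.
#' @export
takens_embed <- function(x, m = "auto", lag = "auto", fs = NULL,
                         fnn_tol = 0.01, m_max = 10) {
  if (inherits(x, "avol_ts")) {
    if (is.null(fs)) fs <- x$fs
    x <- ts_channel(x)
  }
  stopifnot(is.numeric(x))
  N <- length(x)
  if (identical(lag, "auto")) lag <- select_lag_ami(x)
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  if (identical(m, "auto")) m <- select_dim_fnn(x, lag, tol = fnn_tol,
                                                m_max = m_max)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  npt <- N - (m - 1L) * lag
  if (npt <= 10L)
    stop("series too short: need N > (m - 1) * lag + 10")
  pts <- matrix(0, nrow = npt, ncol = m)
  for (k in seq_len(m)) pts[, k] <- x[(k - 1L) * lag + seq_len(npt)]
  structure(list(points = pts, m = m, lag = lag, fs = fs),
            class = "embedded_trajectory")
}

#' @export
print.embedded_trajectory <- function(x, ...) {
  cat(sprintf("<embedded_trajectory> %d points, m = %d, lag = %d samples\n",
              nrow(x$points), x$m, x$lag))
  invisible(x)
}

#' Embedding delay from average mutual information
#'
#' Computes the average mutual information between `x(t)` and `x(t + lag)`
#' over a histogram estimate and returns the first local minimum, the
#' standard heuristic for the Takens embedding delay.
#'
#' @param x Numeric vector.
#' @param max_lag Largest lag searched (default `N / 4`).
#' @param bins Histogram bins per axis.
#' @return Integer lag (samples).
#' @export
select_lag_ami <- function(x, max_lag = floor(length(x) / 4), bins = 16) {
  stopifnot(is.numeric(x), length(x) >= 20)
  if (sd(x) == 0) stop("constant signal: mutual information undefined")
  ami <- ami_cpp(x, as.integer(max_lag), as.integer(bins))
  for (k in seq_len(length(ami) - 1L)) {
    if (!is.na(ami[k + 1L]) && ami[k + 1L] > ami[k]) return(k)
  }
  stop("no local minimum of the average mutual information within lag ",
       max_lag, "; supply `lag` manually")
}

#' Embedding dimension from false nearest neighbours
#'
#' Kennel false-nearest-neighbour criterion: for each trial dimension `m` the
#' fraction of nearest-neighbour pairs whose separation grows anomalously
#' when a coordinate is added; the smallest `m` with fraction below `tol` is
#' returned.
#'
#' @param x Numeric vector.
#' @param lag Embedding delay (samples).
#' @param tol Acceptable FNN fraction.
#' @param m_max Largest dimension tried.
#' @param rtol,atol Kennel thresholds.
#' @return Integer dimension; if no `m <= m_max` reaches `tol`, returns
#'   `m_max` with a warning.
#' @export
select_dim_fnn <- function(x, lag, tol = 0.01, m_max = 10, rtol = 10,
                           atol = 2) {
  stopifnot(is.numeric(x), lag >= 1)
  sdx <- sd(x)
  # subsample long series: FNN needs O(N^2) work
  if (length(x) > 3000) x <- x[seq_len(3000)]
  for (m in seq_len(m_max)) {
    npt <- length(x) - m * lag
    if (npt < 50) break
    pts <- matrix(0, nrow = npt, ncol = m)
    for (k in seq_len(m)) pts[, k] <- x[(k - 1L) * lag + seq_len(npt)]
    xnext <- x[m * lag + seq_len(npt)]
    f <- fnn_fraction_cpp(pts, xnext, as.integer(lag), rtol, atol, sdx)
    if (!is.na(f) && f < tol) return(m)
  }
  warning("false-nearest-neighbour fraction did not reach ", tol,
          " by m = ", m_max)
  m_max
}

#' Grassberger-Procaccia correlation dimension
#'
#' Estimates the correlation dimension D2 as the slope of `log C(r)` versus
#' `log r`, where `C(r)` is the fraction of point pairs (Chebyshev norm,
#' temporal neighbours within the Theiler window excluded) closer than `r`.
#' The scaling region is selected automatically as the longest run of
#' consecutive radii whose local slopes have SD below `slope_sd_frac` times
#' their mean; the fit quality over that region is reported and the estimate
#' is flagged unreliable when no region with R-squared above `min_r2` exists.
#'
#' @param traj An `embedded_trajectory` from [takens_embed()].
#' @param n_radii Number of log-spaced radii.
#' @param theiler Theiler exclusion window in samples (default `lag * m`).
#' @param slope_sd_frac Scaling-region homogeneity threshold (SD of local
#'   slopes below this fraction of their mean).
#' @param min_r2 Minimum R-squared for a reliable fit.
#' @param min_region Minimum number of radii in the scaling region.
#' @return List of class `chaos_metric`: `value` (D2), `r2`, `reliable`,
#'   `radii`, `corr_sum`, `region` (indices of the fitted radii).
#' @export
correlation_dimension <- function(traj, n_radii = 24, theiler = NULL,
                                  slope_sd_frac = 0.04, min_r2 = 0.98,
                                  min_region = 5) {
  stopifnot(inherits(traj, "embedded_trajectory"))
  pts <- traj$points
  N <- nrow(pts)
  if (N < 200) stop("too few embedded points for a dimension estimate")
  if (is.null(theiler)) theiler <- traj$lag * traj$m
  # radius range from the attractor extent
  ext <- max(apply(pts, 2, function(c) diff(range(c))))
  radii <- exp(seq(log(ext * 5e-3), log(ext * 0.5), length.out = n_radii))
  cs <- gp_corr_sum_cpp(pts, radii, as.integer(theiler))
  keep <- cs > 0
  lr <- log(radii[keep])
  lc <- log(cs[keep])
  if (sum(keep) < min_region + 1)
    return(structure(list(value = NA_real_, r2 = NA_real_, reliable = FALSE,
                          radii = radii, corr_sum = cs, region = integer()),
                     class = "chaos_metric"))
  slopes <- diff(lc) / diff(lr)
  # candidate scaling regions: exclude the saturation knee (C approaching 1,
  # here C > 0.3) and regions whose slope approaches the embedding dimension
  # (the noise floor, which fills the embedding space)
  n_ok <- sum(lc <= log(0.3))
  best <- select_scaling_region(slopes[seq_len(max(0, n_ok - 1L))],
                                slope_sd_frac, min_region,
                                max_slope = 0.8 * traj$m)
  fit_region <- function(idx) {
    f <- lm(lc[idx] ~ lr[idx])
    list(slope = unname(coef(f)[2]), r2 = summary(f)$r.squared)
  }
  if (is.null(best)) {
    # no homogeneous scaling region: the curve is a smooth crossover (e.g.
    # a noisy attractor). Fit the statistically best-supported range of the
    # correlation sum, away from sparse small-radius counts and from the
    # large-radius knee where C(r) approaches 1.
    idx <- which(cs[keep] >= 0.01 & cs[keep] <= 0.3)
    if (length(idx) < min_region) idx <- seq_along(lr)
    f <- fit_region(idx)
    idxk <- which(keep)[idx]
    return(structure(list(value = f$slope, r2 = f$r2,
                          reliable = f$r2 >= min_r2 &&
                            f$slope <= 0.85 * traj$m,
                          radii = radii,
                          corr_sum = cs, region = idxk),
                     class = "chaos_metric"))
  }
  idx <- best[1]:(best[2] + 1L)   # slopes k uses radii k, k+1
  f <- fit_region(idx)
  # an estimate close to the embedding dimension means the attractor was not
  # resolved (noise-like filling of the embedding space)
  saturated <- f$slope > 0.85 * traj$m
  structure(list(value = f$slope, r2 = f$r2,
                 reliable = f$r2 >= min_r2 && !saturated,
                 radii = radii, corr_sum = cs, region = which(keep)[idx]),
            class = "chaos_metric")
}

# longest run of consecutive local slopes with SD < frac * |mean|
# (and mean slope below max_slope, if given)
select_scaling_region <- function(slopes, frac, min_region,
                                  max_slope = Inf) {
  n <- length(slopes)
  best <- NULL
  for (len in rev(seq(min_region - 1L, n))) {
    for (s in seq_len(n - len + 1L)) {
      w <- slopes[s:(s + len - 1L)]
      mu <- mean(w)
      if (mu <= 0 || mu > max_slope) next
      if (sd(w) < frac * mu) {
        best <- c(s, s + len - 1L)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' @export
print.chaos_metric <- function(x, ...) {
  cat(sprintf("value = %.4g (r2 = %.4f, %s)\n", x$value, x$r2,
              if (isTRUE(x$reliable)) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For every embedded point the nearest neighbour outside the Theiler window
#' is found and the mean log separation is tracked forward in time; the slope
#' of the initial linear segment of that divergence curve is the largest
#' Lyapunov exponent. Reported in natural-log units per second when the
#' trajectory has a sampling rate, otherwise per sample.
#'
#' @param traj An `embedded_trajectory`.
#' @param k_max Steps of divergence tracked (default `N / 8`, capped at 400).
#' @param fit_range Fractions of the divergence rise (initial value to
#'   saturation) bounding the fitted segment; the default skips the early
#'   alignment transient and stops well before saturation.
#' @param theiler Theiler window (default `lag * m`).
#' @param min_r2 Below this fit R-squared the estimate is flagged unreliable
#'   (e.g. immediate saturation for noise-like signals).
#' @return List of class `chaos_metric`: `value` (lambda1), `r2`, `reliable`,
#'   `curve` (mean log divergence), `t_step` (s per divergence step).
#' @export
lyapunov_largest <- function(traj, k_max = NULL, fit_range = c(0.1, 0.6),
                             theiler = NULL, min_r2 = 0.90) {
  stopifnot(inherits(traj, "embedded_trajectory"))
  N <- nrow(traj$points)
  if (N < 200) stop("too few embedded points for a Lyapunov estimate")
  if (is.null(theiler)) theiler <- traj$lag * traj$m
  if (is.null(k_max)) k_max <- max(20L, min(as.integer(N / 8), 400L))
  curve <- rosenstein_cpp(traj$points, as.integer(theiler),
                          as.integer(k_max))
  t_step <- if (is.null(traj$fs)) 1 else 1 / traj$fs
  ext <- max(apply(traj$points, 2, function(c) diff(range(c))))
  # numerically coincident neighbours (noise-free periodic orbit): no
  # measurable divergence
  if (exp(curve[1]) < 1e-8 * ext)
    return(structure(list(value = 0, r2 = NA_real_, reliable = TRUE,
                          curve = curve, t_step = t_step),
                     class = "chaos_metric"))
  # fast saturation: the neighbour separation is dominated by the noise
  # floor (noisy limit cycle, or noise-like signal when it is immediate);
  # the meaningful exponent is the residual post-saturation slope
  rise0 <- max(curve, na.rm = TRUE) - curve[1]
  k_sat <- which(curve >= curve[1] + 0.9 * rise0)[1]
  if (!is.na(k_sat) && k_sat <= 0.3 * length(curve)) {
    idx <- k_sat:length(curve)
    f <- lm(curve[idx] ~ idx)
    return(structure(list(value = unname(coef(f)[2]) / t_step,
                          r2 = summary(f)$r.squared,
                          reliable = k_sat >= 8,
                          curve = curve, t_step = t_step),
                     class = "chaos_metric"))
  }
  # prefer the longest run of stable local slope (skips the early
  # neighbour-alignment transient and the saturation knee)
  idx <- NULL
  stp <- max(1L, floor(length(curve) / 30))
  ks <- seq(1L, length(curve) - stp, by = stp)
  lsl <- (curve[ks + stp] - curve[ks]) / stp
  run <- select_scaling_region(lsl, 0.15, 4)
  if (!is.null(run)) idx <- seq(ks[run[1]], ks[run[2]] + stp)
  if (is.null(idx)) {
    rise <- max(curve, na.rm = TRUE) - curve[1]
    lo <- curve[1] + fit_range[1] * rise
    hi <- curve[1] + fit_range[2] * rise
    sat <- which.max(curve)
    idx <- which(curve >= lo & curve <= hi)
    idx <- idx[idx <= sat]
  }
  if (length(idx) < 5) {
    # immediate saturation: noise-like signal, slope meaningless
    idx2 <- seq_len(min(10L, length(curve)))
    k <- idx2 - 1L
    f <- lm(curve[idx2] ~ k)
    return(structure(list(value = unname(coef(f)[2]) / t_step,
                          r2 = summary(f)$r.squared, reliable = FALSE,
                          curve = curve, t_step = t_step),
                     class = "chaos_metric"))
  }
  k <- idx - 1L
  f <- lm(curve[idx] ~ k)
  slope <- unname(coef(f)[2])           # nats per sample
  r2 <- summary(f)$r.squared
  structure(list(value = slope / t_step, r2 = r2,
                 reliable = r2 >= min_r2 || abs(slope) < 1e-3,
                 curve = curve, t_step = t_step),
            class = "chaos_metric")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample entropy
#'
#' SampEn(m, r): negative log of the conditional probability that sequences
#' matching for `m` points (Chebyshev norm, tolerance `r`) also match for
#' `m + 1`, self-matches excluded. Zero for constant or perfectly repeating
#' signals; larger for more disordered ones.
#'
#' @param x Numeric vector or [avol_ts()] (first channel).
#' @param m Template length.
#' @param r Tolerance as a fraction of the signal SD.
#' @param cap Value reported (with `reliable = FALSE`) when no `m + 1`
#'   template matches exist.
#' @return List of class `chaos_metric` with `value`, `reliable`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, cap = 10) {
  if (inherits(x, "avol_ts")) x <- ts_channel(x)
  stopifnot(is.numeric(x), length(x) >= 50)
  sdx <- sd(x)
  if (sdx == 0)
    return(structure(list(value = 0, reliable = TRUE),
                     class = "chaos_metric"))
  res <- sampen_cpp(x, as.integer(m), r * sdx)
  if (res$B == 0 || res$A == 0)
    return(structure(list(value = cap, reliable = FALSE),
                     class = "chaos_metric"))
  structure(list(value = -log(res$A / res$B), reliable = TRUE),
            class = "chaos_metric")
}

#' Hann-windowed spectrogram with band summaries
#'
#' Short-time Fourier power with a Hann window, plus mean power in the
#' canonical EEG bands (see [eeg_bands()]).
#'
#' @param x Numeric vector or [avol_ts()].
#' @param fs Sampling rate, Hz (from `x` when an `avol_ts`).
#' @param window Window length, ms.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return List of class `avol_spectrogram`: `t` (s), `f` (Hz), `power`
#'   (frequency x time), `band_power` (band x time matrix), `band_total`
#'   (named vector), `dominant_freq` (Hz, overall peak of the mean spectrum),
#'   `dominant_band`.
#' @export
spectrogram <- function(x, fs = NULL, window = 500, overlap = 0.5) {
  if (inherits(x, "avol_ts")) {
    if (is.null(fs)) fs <- x$fs
    x <- ts_channel(x)
  }
  stopifnot(is.numeric(x), !is.null(fs), overlap >= 0, overlap < 1)
  nwin <- round(window / 1000 * fs)
  if (nwin > length(x)) stop("window longer than signal")
  if (nwin < 8) stop("window too short")
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  nf <- floor(nwin / 2)
  f <- (seq_len(nf)) * fs / nwin
  pw <- matrix(0, nrow = nf, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k] + seq_len(nwin) - 1L]
    seg <- (seg - mean(seg)) * hann
    sp <- Mod(fft(seg))^2 / sum(hann^2)
    pw[, k] <- sp[2:(nf + 1L)]
  }
  bands <- eeg_bands()
  bp <- t(vapply(bands, function(b) {
    sel <- f >= b[1] & f < b[2]
    if (!any(sel)) return(numeric(ncol(pw)))
    colMeans(pw[sel, , drop = FALSE])
  }, numeric(ncol(pw))))
  mean_spec <- rowMeans(pw)
  dom_f <- f[which.max(mean_spec)]
  bt <- rowMeans(bp)
  structure(list(t = (starts + nwin / 2) / fs, f = f, power = pw,
                 band_power = bp, band_total = bt,
                 dominant_freq = dom_f,
                 dominant_band = names(bands)[which.max(bt)]),
            class = "avol_spectrogram")
}

#' Dominant frequency of a signal
#'
#' Peak of the Welch-style mean spectrum, restricted to `range` (Hz).
#'
#' @inheritParams spectrogram
#' @param range Frequency search interval, Hz.
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(x, fs = NULL, range = c(1, 100),
                               window = 1000) {
  if (inherits(x, "avol_ts")) {
    if (is.null(fs)) fs <- x$fs
    x <- ts_channel(x)
  }
  window <- min(window, length(x) / fs * 1000)
  sg <- spectrogram(x, fs, window = window, overlap = 0.5)
  sel <- sg$f >= range[1] & sg$f <= range[2]
  sg$f[sel][which.max(rowMeans(sg$power)[sel])]
}

# zero-phase FIR band-pass: order = n_cycles periods of the band low edge
bandpass <- function(x, fs, band, n_cycles = 3) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  ord <- round(n_cycles * fs / band[1])
  ord <- min(ord, floor((length(x) - 2) / 3))
  if (ord < 8)
    stop("signal too short for the requested band (need >= 3 filter cycles)")
  if (ord %% 2 == 1) ord <- ord + 1
  h <- signal::fir1(ord, band * 2 / fs, type = "pass")
  as.numeric(signal::filtfilt(h, x))
}

# analytic signal via FFT (Marple method)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-amplitude coupling by mean vector length
#'
#' Band-passes the phase and amplitude bands with zero-phase FIR filters,
#' extracts the Hilbert phase of the slow band and Hilbert amplitude envelope
#' of the fast band, and computes the amplitude-weighted mean vector length
#' `|mean(A * exp(i phi))| / mean(A)` in `[0, 1]`. Significance is assessed
#' against circular time-shift surrogates of the amplitude series.
#'
#' @param x Numeric vector or [avol_ts()]; for a pair, `y` carries the
#'   amplitude signal (phase from `x`).
#' @param y Optional second signal (amplitude side).
#' @param fs Sampling rate, Hz.
#' @param phase_band,amp_band Two-element Hz intervals; must not overlap.
#' @param n_surrogates Number of circular-shift surrogates (>= 200 advised).
#' @param seed Seed for the surrogate shifts.
#' @return List of class `pac_result`: `mvl`, `surrogate_p`, `phase_band`,
#'   `amp_band`, `surrogates`.
#' @export
pac_mvl <- function(x, y = NULL, fs = NULL, phase_band = c(4, 8),
                    amp_band = c(30, 80), n_surrogates = 200, seed = 1L) {
  if (inherits(x, "avol_ts")) {
    if (is.null(fs)) fs <- x$fs
    x <- ts_channel(x)
  }
  if (inherits(y, "avol_ts")) y <- ts_channel(y)
  if (is.null(y)) y <- x
  stopifnot(!is.null(fs), length(x) == length(y))
  if (max(phase_band[1], amp_band[1]) < min(phase_band[2], amp_band[2]))
    stop("phase and amplitude bands overlap")
  n_cyc <- length(x) / fs * phase_band[1]
  if (n_cyc < 10)
    stop("need >= 10 cycles of the phase band (have ", round(n_cyc, 1), ")")
  ph <- Arg(analytic_signal(bandpass(x, fs, phase_band)))
  am <- Mod(analytic_signal(bandpass(y, fs, amp_band)))
  # trim filter edges
  edge <- round(fs / phase_band[1])
  keep <- (edge + 1):(length(x) - edge)
  ph <- ph[keep]
  am <- am[keep]
  mvl <- function(a, p) Mod(mean(a * exp(1i * p))) / mean(a)
  obs <- mvl(am, ph)
  n <- length(am)
  shifts <- local_rng(seed, sample.int(n - 2L, n_surrogates, replace = TRUE))
  sur <- vapply(shifts, function(s) {
    mvl(c(am[(s + 1):n], am[1:s]), ph)
  }, 0)
  p <- (1 + sum(sur >= obs)) / (n_surrogates + 1)
  structure(list(mvl = obs, surrogate_p = p, phase_band = phase_band,
                 amp_band = amp_band, surrogates = sur),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("PAC mvl = %.3f (phase %g-%g Hz, amp %g-%g Hz), surrogate p = %.4f\n",
              x$mvl, x$phase_band[1], x$phase_band[2], x$amp_band[1],
              x$amp_band[2], x$surrogate_p))
  invisible(x)
}

#' Full chaos-metric panel for one signal
#'
#' Convenience wrapper: delay-embeds the signal and returns correlation
#' dimension, largest Lyapunov exponent and sample entropy with quality
#' flags.
#'
#' @param x Numeric vector or [avol_ts()].
#' @param fs Sampling rate (Hz) when `x` is a bare vector.
#' @param m,lag Passed to [takens_embed()].
#' @return List of class `chaos_metrics` with elements `d2`, `lyap1`,
#'   `entropy` (each a `chaos_metric`), and `m`, `lag`.
#' @export
chaos_metrics <- function(x, fs = NULL, m = "auto", lag = "auto") {
  if (inherits(x, "avol_ts")) {
    if (is.null(fs)) fs <- x$fs
    x <- ts_channel(x)
  }
  traj <- takens_embed(x, m = m, lag = lag, fs = fs)
  structure(list(d2 = correlation_dimension(traj),
                 lyap1 = lyapunov_largest(traj),
                 entropy = sample_entropy(x),
                 m = traj$m, lag = traj$lag),
            class = "chaos_metrics")
}

#' @export
print.chaos_metrics <- function(x, ...) {
  cat(sprintf("D2 = %.3g | lambda1 = %.3g | SampEn = %.3g (m = %d, lag = %d)\n",
              x$d2$value, x$lyap1$value, x$entropy$value, x$m, x$lag))
  invisible(x)
}
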