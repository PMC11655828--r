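#' Benchmark signal specification
#'
#' Deterministic generators of reference signals with known nonlinear-
#' dynamics properties, used as oracles for the analysis battery:
#' `sine` (limit cycle, D2 = 1, lambda1 <= 0), `white_noise`, `lorenz`
#' (D2 about 2.06, lambda1 about 0.9 per model time unit at the standard
#' parameters), `rossler`, `theta_modulated_gamma` (strong 6->40 Hz
#' phase-amplitude coupling) and `ar_colored_noise`.
#'
#' @param kind One of `"sine"`, `"white_noise"`, `"lorenz"`, `"rossler"`,
#'   `"theta_modulated_gamma"`, `"ar_colored_noise"`.
#' @param n Number of samples.
#' @param fs Sampling rate, Hz. For the chaotic flows `1/fs` is the
#'   integration output step in model time units (e.g. `fs = 100` gives the
#'   conventional Lorenz step 0.01).
#' @param params Named list of per-kind parameters; unset entries take the
#'   defaults listed in [generate_fixture()].
#' @param seed Integer seed (noise-bearing kinds).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, n = 2000, fs = 1000, params = list(),
                         seed = 1L) {
  kind <- match.arg(kind, c("sine", "white_noise", "lorenz", "rossler",
                            "theta_modulated_gamma", "ar_colored_noise"))
  stopifnot(n >= 10, fs > 0)
  structure(list(kind = kind, n = as.integer(n), fs = fs, params = params,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a benchmark signal
#'
#' Realises a [fixture_spec()] deterministically. Parameter defaults:
#' * `sine`: `freq = 10` Hz, `amplitude = 1`, `phase = 0`, `noise_sd = 0`.
#' * `white_noise`: `sd = 1`.
#' * `lorenz`: `sigma = 10`, `rho = 28`, `beta = 8/3`, integrated with an
#'   adaptive Runge-Kutta (`deSolve::ode`, "ode45"), 10 time units of
#'   transient discarded, `x` coordinate returned.
#' * `rossler`: `a = 0.2`, `b = 0.2`, `c = 5.7`, 50 time units transient.
#' * `theta_modulated_gamma`: `f_phase = 6`, `f_amp = 40`, `depth = 1`,
#'   `sharpness = 2`, `slow_amp = 1`, `noise_sd = 0.05`;
#'   `s(t) = slow_amp cos(p) + [(1 + depth cos(p)) / (1 + depth)]^sharpness
#'   cos(2 pi f_amp t) + noise` where the phase `p` advances at `f_phase`
#'   with a slow seeded frequency drift (`freq_drift = 0.05` relative). The
#'   slow term makes the modulating phase recoverable from the composite
#'   signal (with the defaults the amplitude-weighted mean vector length is
#'   2/3 analytically); the drift makes time-shift surrogates decorrelate,
#'   as they do for physiological rhythms.
#' * `ar_colored_noise`: `phi = 0.95`, `sd = 1` (AR(1)).
#'
#' @param spec A [fixture_spec()].
#' @return An [avol_ts()] with one channel `x`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$params
  def <- function(name, val) if (is.null(p[[name]])) val else p[[name]]
  n <- spec$n
  fs <- spec$fs
  tt <- (seq_len(n) - 1) / fs
  x <- switch(spec$kind,
    sine = {
      a <- def("amplitude", 1)
      s <- a * sin(2 * pi * def("freq", 10) * tt + def("phase", 0))
      nsd <- def("noise_sd", 0)
      if (nsd > 0) s <- s + local_rng(spec$seed, rnorm(n, 0, nsd))
      s
    },
    white_noise = local_rng(spec$seed, rnorm(n, 0, def("sd", 1))),
    lorenz = {
      pars <- c(sigma = def("sigma", 10), rho = def("rho", 28),
                beta = def("beta", 8 / 3))
      f <- function(t, y, pr) {
        list(c(pr["sigma"] * (y[2] - y[1]),
               y[1] * (pr["rho"] - y[3]) - y[2],
               y[1] * y[2] - pr["beta"] * y[3]))
      }
      trans <- def("transient", 10)
      times <- seq(0, trans + (n - 1) / fs, by = 1 / fs)
      sol <- deSolve::ode(c(x = 1, y = 1, z = 1), times, f, pars,
                          method = "ode45", rtol = 1e-8, atol = 1e-8)
      tail(sol[, "x"], n)
    },
    rossler = {
      pars <- c(a = def("a", 0.2), b = def("b", 0.2), c = def("c", 5.7))
      f <- function(t, y, pr) {
        list(c(-y[2] - y[3],
               y[1] + pr["a"] * y[2],
               pr["b"] + y[3] * (y[1] - pr["c"])))
      }
      trans <- def("transient", 50)
      times <- seq(0, trans + (n - 1) / fs, by = 1 / fs)
      sol <- deSolve::ode(c(x = 1, y = 1, z = 0), times, f, pars,
                          method = "ode45", rtol = 1e-8, atol = 1e-8)
      tail(sol[, "x"], n)
    },
    theta_modulated_gamma = {
      depth <- def("depth", 1)
      fm <- def("freq_drift", 0.05)
      drift <- if (fm > 0) local_rng(spec$seed + 1L, {
        z <- stats::filter(rnorm(n), 0.999, method = "recursive")
        as.numeric(z) / max(sd(z), 1e-12)
      }) else numeric(n)
      ph <- 2 * pi * def("f_phase", 6) * cumsum(1 + fm * drift) / fs
      env <- ((1 + depth * cos(ph)) / (1 + depth))^def("sharpness", 2)
      s <- def("slow_amp", 1) * cos(ph) +
        env * cos(2 * pi * def("f_amp", 40) * tt)
      nsd <- def("noise_sd", 0.05)
      if (nsd > 0) s <- s + local_rng(spec$seed, rnorm(n, 0, nsd))
      s
    },
    ar_colored_noise = {
      phi <- def("phi", 0.95)
      local_rng(spec$seed, {
        e <- rnorm(n, 0, def("sd", 1))
        s <- numeric(n)
        s[1] <- e[1]
        for (k in 2:n) s[k] <- phi * s[k - 1] + e[k]
        s
      })
    })
  avol_ts(list(x = x), fs = fs,
          meta = list(fixture = spec$kind, params = p, seed = spec$seed))
}
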