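#' Stimulus specification
#'
#' An external or internal input targeting excitatory-layer units: afferent
#' fibres never contact the inhibitory layers, so `target_units` must lie in
#' the excitatory layer (the only exception, feed-forward inhibition driven
#' through long-range projections, is handled by [projection()] targets, not
#' by stimuli). The waveform gives the input current in potential-units/ms as
#' a function of time in ms; it is gated by `[onset, offset)`.
#'
#' @param target_units Integer vector of unit indices (excitatory layer).
#' @param waveform Function of time (ms) returning the drive, or a single
#'   constant.
#' @param label `"external"` or `"internal"`.
#' @param onset,offset Gate interval, ms (`offset = Inf` keeps it on).
#' @param weights Per-target multipliers (recycled).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_units, waveform, label = "external",
                          onset = 0, offset = Inf, weights = 1) {
  stopifnot(length(target_units) >= 1L)
  if (is.numeric(waveform) && length(waveform) == 1L) {
    amp <- waveform
    waveform <- function(t) rep(amp, length(t))
  }
  stopifnot(is.function(waveform))
  label <- match.arg(label, c("external", "internal"))
  structure(list(target_units = as.integer(target_units),
                 waveform = waveform, label = label,
                 onset = onset, offset = offset,
                 weights = rep_len(weights, length(target_units))),
            class = "stimulus_spec")
}

check_stimuli <- function(state, stimuli) {
  for (s in stimuli) {
    stopifnot(inherits(s, "stimulus_spec"))
    if (any(s$target_units < 1L | s$target_units > state$n))
      stop("stimulus target out of range")
    lay <- state$layer[s$target_units]
    if (any(lay == "FB"))
      stop("no afferent may contact the feedback inhibitory layer")
    # feed-forward inhibitory targets are reserved for projection-mediated
    # feed-forward inhibition (see acc_ba46_feedforward)
    if (any(lay == "FF") && !isTRUE(attr(s, "ff_ok")))
      stop("stimulus targets must lie in the excitatory layer")
  }
  invisible(TRUE)
}

delay_steps <- function(d_ms, dt) {
  steps <- d_ms / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("conduction delays must be integer multiples of dt (dt = ", dt,
         " ms)")
  as.integer(round(steps))
}

# allocate / validate the delay history ring buffer for step size dt
ensure_gbuf <- function(state, dt) {
  ds <- delay_steps(state$con$d, dt)
  depth <- max(ds, 0L) + 1L
  if (is.null(state$gbuf) || is.null(state$dt) || state$dt != dt ||
      nrow(state$gbuf) < depth) {
    g0 <- state$C * state$Q * (1 - exp(-exp(state$u) / state$Q))
    state$gbuf <- matrix(rep(g0, each = depth), nrow = depth)
    state$gpos <- 0L
    state$dt <- dt
  }
  state
}

#' Advance a network by an arbitrary duration
#'
#' Low-level driver around the compiled Euler-Maruyama integrator of
#' `du_i/dt = -u_i/tau_i + sum_j w_ij g_j(u_j(t - d_ij)) + I_i(t) + xi(t)`.
#' Delayed gains are read from a ring buffer; the noise term is an independent
#' Gaussian increment of SD `noise_sd * sqrt(dt)` per unit and step. When
#' `learning = TRUE`, every plastic weight is updated each step by the
#' saturating Hebbian rule (see [hebbian_update()]).
#'
#' @param state A `network_state` (from [build_area()] or [build_brain()]
#'   flattening).
#' @param stimuli List of [stimulus_spec()] objects.
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms.
#' @param learning Logical; apply Hebbian updates each step.
#' @param seed Optional integer; when given, seeds the noise stream (runs are
#'   then bit-reproducible).
#' @param record_every Record every `record_every`-th step.
#' @param probes Named list of unit-index vectors; for each probe the mean
#'   membrane potential and mean gain output are recorded. Default: mean over
#'   the excitatory layer.
#' @return List with `state` (advanced copy) and `ts` (an [avol_ts()] whose
#'   channels are `<probe>` mean potentials and `<probe>.g` mean gains).
#' @export
run_net <- function(state, stimuli = list(), duration, dt = 0.1,
                    learning = FALSE, seed = NULL, record_every = 10L,
                    probes = NULL) {
  stopifnot(inherits(state, "network_state"), duration >= dt, dt > 0)
  check_stimuli(state, stimuli)
  if (is.null(probes)) probes <- list(E = state$idx_e)
  stopifnot(length(probes) >= 1L, !is.null(names(probes)))
  state <- ensure_gbuf(state, dt)
  n_steps <- as.integer(round(duration / dt))
  ds <- delay_steps(state$con$d, dt)

  t_grid <- state$t + (seq_len(n_steps) - 1L) * dt
  stim_wave <- matrix(0, nrow = n_steps, ncol = length(stimuli))
  stim_targets <- list()
  stim_weights <- list()
  for (k in seq_along(stimuli)) {
    s <- stimuli[[k]]
    on <- t_grid >= s$onset & t_grid < s$offset
    a <- numeric(n_steps)
    if (any(on)) a[on] <- s$waveform(t_grid[on])
    stim_wave[, k] <- a
    stim_targets[[k]] <- s$target_units - 1L
    stim_weights[[k]] <- s$weights
  }

  run <- function() sim_net_cpp(
    state$u, state$gbuf, state$gpos,
    state$con$i - 1L, state$con$j - 1L, state$con$w, ds,
    state$con$plastic, state$con$eta, state$con$wmax,
    state$tau, state$Q, state$C, state$noise_sd, state$tonic,
    dt, n_steps, stim_wave, stim_targets, stim_weights,
    isTRUE(learning),
    lapply(probes, function(ix) as.integer(ix) - 1L),
    as.integer(record_every),
    as.integer(round(state$t / dt)) %% as.integer(record_every))
  res <- if (is.null(seed)) run() else local_rng(seed, run())

  out <- state
  out$u <- res$u
  out$gbuf <- res$gbuf
  out$gpos <- res$gpos
  out$con$w <- res$w
  out$t <- state$t + n_steps * dt

  fs <- 1000 / (dt * record_every)
  ch <- c(stats::setNames(lapply(seq_along(probes),
                                 function(p) res$rec_u[, p]),
                          names(probes)),
          stats::setNames(lapply(seq_along(probes),
                                 function(p) res$rec_g[, p]),
                          paste0(names(probes), ".g")))
  base_off <- as.integer(round(state$t / dt)) %% as.integer(record_every)
  t0 <- if (length(res$rec_step)) state$t + (res$rec_step[1] - base_off) * dt
        else state$t
  ts <- avol_ts(ch, fs = fs, t0 = t0,
                meta = list(seed = seed, dt = dt, duration = duration,
                            learning = isTRUE(learning)))
  list(state = out, ts = ts)
}

#' Single integration step
#'
#' Advances the network state by exactly one Euler-Maruyama step of `dt` ms.
#' Convenience wrapper around [run_net()] for inspection and testing.
#'
#' @inheritParams run_net
#' @return The advanced `network_state`.
#' @export
net_step <- function(state, stimuli = list(), dt = 0.1, seed = NULL,
                     learning = FALSE) {
  run_net(state, stimuli, duration = dt, dt = dt, learning = learning,
          seed = seed, record_every = 1L)$state
}

#' Simulate an area and return its EEG-like output
#'
#' S3 method for `stats::simulate` on `network_state`. The default readout is
#' the mean membrane potential of the excitatory layer, the model's EEG-like
#' channel; additional probes (e.g. assemblies) add channels. The advanced
#' state is attached as attribute `"state"`.
#'
#' @param object A `network_state`.
#' @param nsim Unused (one realisation per call).
#' @param seed Integer seed for the noise stream.
#' @param stimuli List of [stimulus_spec()].
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms.
#' @param learning Logical; Hebbian plasticity on.
#' @param record_every Sample every this many steps.
#' @param probes Optional named list of unit-index vectors.
#' @param ... Unused.
#' @return An [avol_ts()]; attribute `"state"` holds the final state.
#' @export
simulate.network_state <- function(object, nsim = 1, seed = NULL, ...,
                                   stimuli = list(), duration = 1000,
                                   dt = 0.1, learning = FALSE,
                                   record_every = 10L, probes = NULL) {
  res <- run_net(object, stimuli, duration, dt, learning, seed,
                 record_every, probes)
  out <- res$ts
  attr(out, "state") <- res$state
  out
}

#' Saturating Hebbian weight update
#'
#' Applies one learning increment
#' `dw_ij = eta * dt * g_i(u_i(t)) * g_j(u_j(t - d_ij)) * (w_max - w_ij)` to
#' every plastic (excitatory-source) connection. Because the increment is
#' proportional to `(w_max - w_ij)` and gains are non-negative, weights can
#' approach but never exceed `w_max`, and never decrease below 0. Inhibitory
#' weights and absent (zero-pattern) connections are untouched. The `eta`
#' stored per connection is a rate per ms, so results are robust to the
#' integration step.
#'
#' The discrete rate `eta * dt * g_i * g_j` is capped at 1 so the bound
#' survives arbitrarily large steps exactly. During integration with
#' `learning = TRUE` this same rule is applied inside the compiled core each
#' step; this R implementation is the reference used by tests and for
#' single-step updates.
#'
#' @param state A `network_state` with a populated history buffer (after at
#'   least one integration step); if the buffer is absent, current gains are
#'   used for the delayed term.
#' @param dt Step size, ms, scaling the increment.
#' @return The state with updated weights.
#' @export
hebbian_update <- function(state, dt = 0.1) {
  stopifnot(inherits(state, "network_state"), dt > 0)
  con <- state$con
  pl <- which(con$plastic & con$eta > 0)
  if (!length(pl)) return(state)
  g_now <- state$C * state$Q * (1 - exp(-exp(state$u) / state$Q))
  if (!is.null(state$gbuf)) {
    ds <- delay_steps(con$d[pl], state$dt)
    depth <- nrow(state$gbuf)
    rows <- ((state$gpos - ds) %% depth) + 1L
    g_del <- state$gbuf[cbind(rows, con$j[pl])]
  } else {
    g_del <- g_now[con$j[pl]]
  }
  rate <- pmin(con$eta[pl] * dt * g_now[con$i[pl]] * g_del, 1)
  state$con$w[pl] <- con$w[pl] + rate * (con$wmax[pl] - con$w[pl])
  state
}
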