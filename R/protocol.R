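#' Configuration of the intentional-control protocol
#'
#' Settings for the four-stage protocol: (I) presentation of external and
#' internal stimuli and the BA9 attentional gate, (II) salience competition
#' among goal assemblies in BA10, (III) the iterated ACC feedback loop with
#' expectancy-weighted feed-forward drive onto BA46, and (IV) the pre-SMA
#' early readiness-potential readout. One iteration is one fixed-duration
#' simulation epoch followed by salience/expectancy re-weighting, an
#' inhibitory-gain increase for suppressed assemblies, and Hebbian
#' consolidation (plasticity is active throughout deliberate epochs).
#'
#' @param n_iterations Number of feedback iterations in the deliberate mode
#'   (default 12).
#' @param iteration_duration Epoch length, ms; must be at least 10 times the
#'   slowest membrane time constant.
#' @param dt Integration step, ms.
#' @param record_every Record every this many steps (sampling rate is
#'   `1000 / (dt * record_every)` Hz).
#' @param gate_threshold,gate_window,gate_band BA9 gate settings (see
#'   [ba9_gate()]); window in ms.
#' @param rp_smoothing Readiness-potential smoothing time constant, ms.
#' @param awareness_threshold Threshold on |RP| whose crossing time is
#'   reported.
#' @param transient_frac Fraction of each epoch discarded before metric
#'   computation (approximate stationarity for the Takens battery).
#' @param acc_drive,ba9_ctx_drive Tonic endogenous drive to ACC and context
#'   drive to BA9 (potential units/ms). Setting both to 0 gives a
#'   spontaneous, stimulus-free run.
#' @param int_amp,ext_amp,stim_freq,ext_phase Slow (Hz `stim_freq`)
#'   amplitude envelopes of the internal and external stimuli, used by the
#'   Step-I gate; with the default 2 Hz the 500 ms gate window covers one
#'   full period, so `ext_phase = pi/2` (quadrature) gives correlation 0 and
#'   hence the arbitrary pathway.
#' @param goal_amp Base amplitude of the retrieved goal drives onto the BA10
#'   assemblies.
#' @param goal_fade Fraction of the goal-drive forcing that is withdrawn by
#'   the last iteration: as the competition resolves, the retrieved beta
#'   patterns hand over to the assemblies' intrinsic (driven gamma)
#'   dynamics.
#' @param goal_freqs Per-assembly goal-drive frequencies, Hz.
#' @param carrier_gain,carrier_band Carrier stimulus scale and band (Hz).
#' @param boost,suppress,mult_range Salience competition: multiplier offsets
#'   and the clamp range of the cumulative per-assembly multiplier.
#' @param expectancy Per-assembly expectancy weights for BA46 (exogenous,
#'   config-supplied); the assembly with the largest weight is the tracked
#'   assembly.
#' @param ff_base,ff_ramp,ff_ratio,ff_mod ACC->BA46 feedforward drive:
#'   scale is `ff_base + ff_ramp * (it - 1) / (n_iterations - 1)`;
#'   `ff_ratio` is the feed-forward inhibitory fraction and `ff_mod` the
#'   depth of the ACC rhythm riding on the tonic component.
#' @param enh_ramp Peak extra tonic drive to enhanced (salience-winning)
#'   goal assemblies in BA10 and their associated BA46 action assemblies,
#'   reached linearly by the last iteration; raises their operating point
#'   into the driven gamma regime.
#' @param inh_ramp Per-iteration relative increase of inhibitory weights onto
#'   suppressed assemblies (the stabilisation mechanism).
#' @param afferent_gate Fraction of the long-range afferents onto BA10 and
#'   BA46 that is gated away as the deliberation converges (effective
#'   feed-forward inhibitory gating of goal-irrelevant afferent flow);
#'   0 disables gating.
#' @param ramp_frac Fraction of the iterations over which the convergence
#'   schedules (enhancement, feed-forward drive, goal fade, afferent gate)
#'   reach their final values; the remaining iterations hold the converged
#'   regime.
#' @param pretrain_ms,pretrain_amp,pretrain_eta Assembly pre-training
#'   ("loading long-term memories"): duration per assembly, drive amplitude,
#'   learning rate.
#' @param n_surrogates PAC surrogate count.
#' @param seed Master seed; all epoch noise streams and surrogate shifts
#'   derive from it.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_iterations = 12,
                            iteration_duration = 2500,
                            dt = 0.1,
                            record_every = 10L,
                            gate_threshold = 0.3,
                            gate_window = 500,
                            gate_band = NULL,
                            rp_smoothing = 1500,
                            awareness_threshold = 0.5,
                            transient_frac = 0.2,
                            acc_drive = 0.5,
                            ba9_ctx_drive = 0.3,
                            int_amp = 0.3, ext_amp = 0.3,
                            stim_freq = 2, ext_phase = 0,
                            goal_amp = 0.5, goal_fade = 1,
                            goal_freqs = c(16, 20, 13, 25),
                            carrier_gain = 0.05,
                            carrier_band = c(4, 8),
                            boost = 0.35, suppress = 0.35,
                            mult_range = c(0.2, 2),
                            expectancy = c(1, 0.3, 0.3, 0.3),
                            ff_base = 0.25, ff_ramp = 0.45, ff_ratio = 0.1,
                            ff_mod = 0.12,
                            enh_ramp = 0.8,
                            inh_ramp = 0.06,
                            afferent_gate = 0.9,
                            ramp_frac = 0.5,
                            pretrain_ms = 150, pretrain_amp = 0.4,
                            pretrain_eta = 8e-4,
                            n_surrogates = 200,
                            seed = 1L) {
  stopifnot(n_iterations >= 1, iteration_duration > 0, dt > 0,
            transient_frac >= 0, transient_frac < 1)
  cfg <- as.list(environment())
  class(cfg) <- "protocol_config"
  cfg
}

# periodic continuation of a recorded waveform, rebased to a new epoch start
looped_waveform <- function(times, values, new_t0, scale = 1) {
  t0 <- times[1]
  len <- times[length(times)] - t0
  if (len <= 0) return(function(t) rep(0, length(t)))
  f <- stats::approxfun(times - t0, values, rule = 2)
  function(t) scale * f((t - new_t0) %% len)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# remove drift slower than ~2.5 Hz (running-mean subtraction) so the Takens
# battery sees the oscillatory content, not the drive envelope
detrend_slow <- function(x, fs, win_ms = 400) {
  w <- max(3L, round(win_ms / 1000 * fs))
  if (w %% 2 == 0) w <- w + 1L
  mu <- stats::filter(x, rep(1 / w, w), sides = 2)
  mu[is.na(mu)] <- mean(x)
  as.numeric(x - mu)
}

#' Pre-train goal and action assemblies
#'
#' Loads "long-term memories": each BA10/BA46 assembly pair is driven at its
#' goal frequency for `pretrain_ms` with Hebbian plasticity enabled at
#' `pretrain_eta`, strengthening intra-assembly excitatory weights. Returns
#' the brain with consolidated weights (learning rates restored).
#'
#' @param brain A `brain_model`.
#' @param cfg A [protocol_config()].
#' @return The brain with updated `net` weights.
#' @export
pretrain_assemblies <- function(brain, cfg = protocol_config()) {
  stopifnot(inherits(brain, "brain_model"))
  if (cfg$pretrain_ms <= 0) return(brain)
  net <- brain$net
  old_eta <- net$con$eta
  net$con$eta[net$con$plastic] <- cfg$pretrain_eta
  n_as <- length(brain$areas$BA10$assemblies)
  for (k in seq_len(n_as)) {
    fk <- cfg$goal_freqs[(k - 1) %% length(cfg$goal_freqs) + 1]
    wf <- local({
      fk0 <- fk
      amp <- cfg$pretrain_amp
      function(t) amp * (1 + sin(2 * pi * fk0 * t / 1000)) / 2
    })
    stim <- stimulus_spec(c(brain_units(brain, "BA10", assembly = k),
                            brain_units(brain, "BA46", assembly = k)),
                          wf, label = "internal")
    res <- run_net(net, list(stim), duration = cfg$pretrain_ms, dt = cfg$dt,
                   learning = TRUE, seed = cfg$seed * 100L + 90L + k,
                   record_every = cfg$record_every)
    net <- res$state
  }
  net$con$eta <- old_eta
  net$u <- rep(0, net$n)     # reset activity, keep consolidated weights
  net$gbuf <- NULL
  net$t <- 0
  brain$net <- net
  brain
}

#' Run the intentional-control protocol
#'
#' Executes the staged protocol on a built brain: a warm-up epoch provides
#' the Step-I gate window and the first ACC carrier estimate; the BA9 gate
#' classifies the run as deliberate (full iterated ACC feedback loop, with
#' Hebbian learning) or arbitrary (single feed-forward pass, ACC propagation
#' suppressed); each iteration simulates one epoch under the current goal
#' drives, carrier and expectancy-weighted BA46 feedforward drive, measures
#' the chaos metrics of the tracked BA46 assembly on the stationary part of
#' the epoch, and re-weights the competition (salience multipliers,
#' inhibitory-gain increase for suppressed assemblies). The pre-SMA drive
#' (gain outputs of BA10 and BA9 excitatory layers, projection-weighted) is
#' accumulated throughout and smoothed into the early readiness potential.
#'
#' @param brain A `brain_model` (assemblies are pre-trained internally
#'   unless `pretrain = FALSE`).
#' @param cfg A [protocol_config()].
#' @param pretrain Run [pretrain_assemblies()] first.
#' @return An object of class `protocol_result`: `iterations` (data frame of
#'   per-iteration metrics: `d2`, `lyap1`, `entropy`, `dom_freq`,
#'   `dom_freq_ba10`, `pac`, embedding `m`/`lag`, reliability flags),
#'   `signals` (list of per-epoch [avol_ts()]), `rp` (an `rp_trace`),
#'   `gate`, `mode`, `multipliers` (final), `config`.
#' @export
run_protocol <- function(brain, cfg = protocol_config(), pretrain = TRUE) {
  stopifnot(inherits(brain, "brain_model"), inherits(cfg, "protocol_config"))
  slowest_tau <- max(brain$net$tau)
  if (cfg$iteration_duration < 10 * slowest_tau)
    stop("iteration_duration must be >= 10x the slowest membrane time ",
         "constant (", slowest_tau, " ms)")
  fs <- 1000 / (cfg$dt * cfg$record_every)
  n_as <- length(brain$areas$BA10$assemblies)
  tracked <- which.max(rep_len(cfg$expectancy, n_as))
  expectancy <- rep_len(cfg$expectancy, n_as)

  # ---- stimulus waveforms ----
  int_wf <- local({
    a <- cfg$acc_drive; m <- cfg$int_amp; f <- cfg$stim_freq
    function(t) a * (1 + m * sin(2 * pi * f * t / 1000))
  })
  ext_wf <- local({
    a <- cfg$ba9_ctx_drive; m <- cfg$ext_amp; f <- cfg$stim_freq
    ph <- cfg$ext_phase
    function(t) a * (1 + m * sin(2 * pi * f * t / 1000 + ph))
  })
  quiescent <- cfg$acc_drive == 0 && cfg$ba9_ctx_drive == 0

  # ---- Step I: gate on the integrated stimulus window ----
  tgate <- seq(0, cfg$gate_window, by = 1000 / fs)
  gate <- NULL
  mode <- "deliberate"
  if (!quiescent) {
    ei <- int_wf(tgate)
    ee <- ext_wf(tgate)
    if (sd(ei) > 0 && sd(ee) > 0) {
      gate <- ba9_gate(ee, ei, threshold = cfg$gate_threshold, fs = fs,
                       band = cfg$gate_band)
      mode <- classify_pathway(gate)
    }
  }
  n_eff <- if (mode == "deliberate") cfg$n_iterations else 1L

  if (pretrain && mode == "deliberate" && !quiescent)
    brain <- pretrain_assemblies(brain, cfg)
  net <- brain$net

  probes <- c(
    lapply(c(ACC = "ACC", BA9 = "BA9", BA10 = "BA10", BA46 = "BA46"),
           function(a) brain_units(brain, a)),
    stats::setNames(lapply(seq_len(n_as), function(k)
      brain_units(brain, "BA10", assembly = k)),
      paste0("BA10.a", seq_len(n_as))),
    stats::setNames(lapply(seq_len(n_as), function(k)
      brain_units(brain, "BA46", assembly = k)),
      paste0("BA46.a", seq_len(n_as))))

  base_stims <- function() {
    s <- list()
    if (cfg$acc_drive > 0)
      s <- c(s, list(stimulus_spec(brain_units(brain, "ACC"),
                                   cfg$acc_drive, label = "internal")))
    if (cfg$ba9_ctx_drive > 0)
      s <- c(s, list(stimulus_spec(brain_units(brain, "BA9"),
                                   cfg$ba9_ctx_drive, label = "external")))
    s
  }
  if (mode == "arbitrary" && !quiescent) {
    # pathway (b): ACC drives BA9's inhibitory interneurons instead
    sup <- stimulus_spec(brain_units(brain, "BA9", layer = "FF"),
                         function(t) int_wf(t) * 0.5, label = "internal")
    attr(sup, "ff_ok") <- TRUE
  }

  # ---- warm-up epoch (initial carrier and operating point) ----
  warm <- tryCatch(
    run_net(net, base_stims(),
            duration = max(cfg$gate_window, 4 * 1000 / cfg$carrier_band[1]),
            dt = cfg$dt, learning = FALSE, seed = cfg$seed * 100L,
            record_every = cfg$record_every, probes = probes),
    error = function(e) stop("simulation diverged in warm-up: ",
                             conditionMessage(e)))
  net <- warm$state
  acc_prev <- avol_ts(list(ACC = warm$ts$channels$ACC), fs = fs,
                      t0 = warm$ts$t0)

  mult <- rep(1, n_as)
  names(mult) <- paste0("a", seq_len(n_as))
  cnorm <- function(t) cos(2 * pi * 6 * t / 1000)   # placeholder carrier
  rows <- vector("list", n_eff)
  signals <- vector("list", n_eff)
  drive <- numeric(0)

  gated <- grepl("^proj_", net$con$class) &
    net$area_of[net$con$i] %in% c("BA10", "BA46")
  # convergence progress: 0 at the first iteration, 1 from
  # ramp_frac * n_iterations onwards
  progress <- function(it) {
    if (n_eff <= 1) return(1)
    min(1, (it - 1) / max(1, (n_eff - 1) * cfg$ramp_frac))
  }
  gate_factor <- function(it) {
    if (n_eff <= 1 || cfg$afferent_gate <= 0) return(1)
    1 - cfg$afferent_gate * progress(it)
  }

  for (it in seq_len(n_eff)) {
    epoch_t0 <- net$t
    mult_epoch <- mult
    if (mode == "deliberate" && !quiescent && it > 1 && any(gated))
      net$con$w[gated] <- net$con$w[gated] *
        gate_factor(it) / gate_factor(it - 1)
    stims <- base_stims()
    if (mode == "arbitrary" && !quiescent) stims <- c(stims, list(sup))

    if (mode == "deliberate" && !quiescent) {
      # carrier from the previous epoch's ACC theta, continued periodically
      carr_stim <- carrier_signal(acc_prev, band = cfg$carrier_band,
                                  targets = c(brain_units(brain, "BA9"),
                                              brain_units(brain, "BA10")),
                                  gain = cfg$carrier_gain)
      carr_ts <- attr(carr_stim, "carrier")
      cw <- looped_waveform(ts_time(carr_ts), ts_channel(carr_ts), epoch_t0,
                            scale = cfg$carrier_gain)
      stims <- c(stims, list(stimulus_spec(c(brain_units(brain, "BA9"),
                                             brain_units(brain, "BA10")),
                                           cw, label = "internal",
                                           onset = epoch_t0)))
      # goal drives: tracked assembly's drive is locked to the carrier
      csd <- sd(ts_channel(carr_ts))
      cnorm <<- if (it == 1 || csd == 0)
        function(t) cos(2 * pi * 6 * t / 1000)
      else
        looped_waveform(ts_time(carr_ts),
                        clamp(ts_channel(carr_ts) / (2 * csd), -1, 1),
                        epoch_t0)
      fade <- 1 - cfg$goal_fade * progress(it)
      for (k in seq_len(n_as)) {
        fk <- cfg$goal_freqs[(k - 1) %% length(cfg$goal_freqs) + 1]
        amp <- cfg$goal_amp * mult[k] * fade
        if (amp <= 0) next
        wf <- local({
          fk0 <- fk; a0 <- amp; locked <- (k == tracked); cn <- cnorm
          function(t) {
            envl <- if (locked) (1 + cn(t)) / 2 else 1
            a0 * envl * sin(2 * pi * fk0 * t / 1000)
          }
        })
        stims <- c(stims, list(stimulus_spec(
          brain_units(brain, "BA10", assembly = k), wf,
          label = "internal", onset = epoch_t0)))
      }
      # cumulative enhancement: winning goal assemblies and their
      # associated action assemblies get ramped tonic drive
      if (it > 1 && cfg$enh_ramp > 0 && n_eff > 1) {
        amp_enh <- cfg$enh_ramp * progress(it)
        for (k in which(mult > 1)) {
          stims <- c(stims, list(stimulus_spec(
            c(brain_units(brain, "BA10", assembly = k),
              brain_units(brain, "BA46", assembly = k)), amp_enh,
            label = "internal", onset = epoch_t0)))
        }
      }
      # expectancy-weighted ACC feedforward drive onto BA46
      ff_scale <- cfg$ff_base + cfg$ff_ramp * progress(it)
      exp_w <- expectancy * clamp(mult, 0.2, 2)
      if (max(exp_w) > 0) exp_w <- exp_w / max(exp_w)
      ffpair <- acc_ba46_feedforward(
        avol_ts(list(ACC = ts_channel(acc_prev)), fs = fs, t0 = epoch_t0),
        brain$areas$BA46, expectancy = exp_w,
        scale = ff_scale, ff_ratio = cfg$ff_ratio, mod = cfg$ff_mod,
        unit_offset = net$offsets[["BA46"]])
      stims <- c(stims, list(ffpair$exc))
      if (!is.null(ffpair$ff)) stims <- c(stims, list(ffpair$ff))
    }

    res <- tryCatch(
      run_net(net, stims, duration = cfg$iteration_duration, dt = cfg$dt,
              learning = (mode == "deliberate" && !quiescent),
              seed = cfg$seed * 100L + it,
              record_every = cfg$record_every, probes = probes),
      error = function(e) stop("simulation diverged at iteration ", it,
                               ": ", conditionMessage(e)))
    net <- res$state
    ts <- res$ts
    signals[[it]] <- ts
    acc_prev <- avol_ts(list(ACC = ts$channels$ACC), fs = fs, t0 = ts$t0)

    # stationary segment
    nrec <- ts_length(ts)
    keep <- seq.int(floor(nrec * cfg$transient_frac) + 1L, nrec)
    seg <- function(ch) ts$channels[[ch]][keep]

    x_tr <- detrend_slow(seg(paste0("BA46.a", tracked)), fs)
    met <- tryCatch(chaos_metrics(x_tr, fs = fs),
                    error = function(e) NULL)
    # PAC needs >= 10 phase-band cycles: use the full epoch, scored
    # against the salience carrier the drives were locked to
    carr_now <- if (mode == "deliberate" && !quiescent)
      cnorm(ts_time(ts))
    else {
      acc_full <- ts$channels$ACC
      bandpass(acc_full - mean(acc_full), fs, cfg$carrier_band)
    }
    pac <- tryCatch(
      pac_mvl(carr_now, ts$channels[[paste0("BA46.a", tracked)]], fs = fs,
              phase_band = cfg$carrier_band, amp_band = c(10, 80),
              n_surrogates = cfg$n_surrogates,
              seed = cfg$seed * 100L + it),
      error = function(e) NULL)

    rows[[it]] <- data.frame(
      iteration = it,
      d2 = if (!is.null(met)) met$d2$value else NA_real_,
      d2_reliable = if (!is.null(met)) met$d2$reliable else FALSE,
      lyap1 = if (!is.null(met)) met$lyap1$value else NA_real_,
      entropy = if (!is.null(met)) met$entropy$value else NA_real_,
      embed_m = if (!is.null(met)) met$m else NA_integer_,
      embed_lag = if (!is.null(met)) met$lag else NA_integer_,
      dom_freq = dominant_frequency(x_tr, fs = fs, range = c(3, 100)),
      dom_freq_ba10 = dominant_frequency(
        detrend_slow(seg(paste0("BA10.a", tracked)), fs), fs = fs,
        range = c(3, 100)),
      pac = if (!is.null(pac)) pac$mvl else NA_real_,
      pac_p = if (!is.null(pac)) pac$surrogate_p else NA_real_)

    # salience competition for the next iteration; once the convergence
    # schedules have saturated the competition is resolved and frozen
    if (mode == "deliberate" && !quiescent && it < n_eff &&
        progress(it + 1) < 1) {
      asg <- stats::setNames(lapply(seq_len(n_as), function(k)
        ts$channels[[paste0("BA10.a", k)]]), paste0("a", seq_len(n_as)))
      m_new <- salience_compete(asg, carr_now, fs = fs,
                                phase_band = cfg$carrier_band,
                                boost = cfg$boost, suppress = cfg$suppress,
                                n_surrogates = cfg$n_surrogates,
                                seed = cfg$seed * 100L + 50L + it)
      mult <- clamp(mult * m_new, cfg$mult_range[1], cfg$mult_range[2])
      supp <- which(m_new < 1)
      if (length(supp) && cfg$inh_ramp > 0) {
        inh_targets <- unlist(c(
          lapply(supp, function(k) brain_units(brain, "BA10", assembly = k)),
          lapply(supp, function(k) brain_units(brain, "BA46", assembly = k))))
        sel <- net$con$class %in% c("ff_e", "fb_e") &
          net$con$i %in% inh_targets
        net$con$w[sel] <- net$con$w[sel] * (1 + cfg$inh_ramp)
      }
    }

    # pre-SMA afferent drive: the efficacy of each assembly's projection
    # follows its enhancement state (synaptic strengthening of enhanced,
    # weakening of suppressed attractor projections)
    wk <- mult_epoch / sum(mult_epoch)
    ba10_drive <- Reduce(`+`, lapply(seq_len(n_as), function(k)
      wk[k] * ts$channels[[paste0("BA10.a", k, ".g")]]))
    drive <- c(drive, brain$config$presma_w_ba10 * ba10_drive +
                 brain$config$presma_w_ba9 * ts$channels$BA9.g)
  }

  drive_ts <- avol_ts(list(presma_drive = drive), fs = fs,
                      t0 = signals[[1]]$t0,
                      meta = list(seed = cfg$seed))
  warm_ba10 <- Reduce(`+`, lapply(seq_len(n_as), function(k)
    warm$ts$channels[[paste0("BA10.a", k, ".g")]])) / n_as
  baseline <- mean(warm_ba10 * brain$config$presma_w_ba10 +
                     warm$ts$channels$BA9.g * brain$config$presma_w_ba9)
  rp <- extract_rp(drive_ts, smoothing = cfg$rp_smoothing,
                   baseline = baseline,
                   awareness_threshold = cfg$awareness_threshold)

  structure(list(iterations = do.call(rbind, rows), signals = signals,
                 rp = rp, gate = gate, mode = mode, multipliers = mult,
                 drive = drive_ts, config = cfg, brain_seed = brain$seed,
                 final_net = net),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  it <- x$iterations
  cat(sprintf("<protocol_result> mode = %s, %d iteration(s)\n", x$mode,
              nrow(it)))
  cat(sprintf("  D2: %.2f -> %.2f | lambda1: %.3g -> %.3g | SampEn: %.2f -> %.2f\n",
              it$d2[1], it$d2[nrow(it)], it$lyap1[1], it$lyap1[nrow(it)],
              it$entropy[1], it$entropy[nrow(it)]))
  cat(sprintf("  dominant freq (BA46): %.1f -> %.1f Hz | RP trend rho = %.3f\n",
              it$dom_freq[1], it$dom_freq[nrow(it)], x$rp$trend_rho))
  invisible(x)
}

#' Early readiness potential from the pre-SMA afferent drive
#'
#' Smooths the summed BA10/BA9 drive into the slow negative-going early
#' readiness potential: an exponential moving average with time constant
#' `smoothing` ms of the (baseline-subtracted) drive, sign-flipped so that
#' growing drive gives a negative-going deflection. The monotone-trend
#' statistic is the Spearman correlation of |amplitude| with time; the
#' threshold crossing is the first time |amplitude| exceeds
#' `awareness_threshold` (NA when it never does, or when no threshold is
#' given).
#'
#' @param presma_drive [avol_ts()] with the summed afferent drive (first
#'   channel), or a numeric vector plus `fs`.
#' @param smoothing EMA time constant, ms (> 0).
#' @param baseline Value subtracted from the drive before smoothing
#'   (default 0).
#' @param awareness_threshold Optional positive threshold on |amplitude|.
#' @param fs Sampling rate when `presma_drive` is a bare vector.
#' @return An object of class `rp_trace`: `time` (ms), `amplitude`
#'   (negative-going), `threshold_crossing` (ms or NA), `trend_rho`.
#' @export
extract_rp <- function(presma_drive, smoothing = 1500, baseline = 0,
                       awareness_threshold = NULL, fs = NULL) {
  if (inherits(presma_drive, "avol_ts")) {
    if (is.null(fs)) fs <- presma_drive$fs
    tms <- ts_time(presma_drive)
    x <- ts_channel(presma_drive)
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(presma_drive)
    tms <- (seq_along(x) - 1) / fs * 1000
  }
  if (smoothing <= 0) stop("smoothing time constant must be > 0")
  alpha <- (1000 / fs) / smoothing
  alpha <- min(alpha, 1)
  d <- x - baseline
  ema <- numeric(length(d))
  acc <- 0
  for (k in seq_along(d)) {
    acc <- acc + alpha * (d[k] - acc)
    ema[k] <- acc
  }
  amplitude <- -ema
  rho <- if (sd(abs(amplitude)) > 0)
    suppressWarnings(cor(abs(amplitude), tms, method = "spearman"))
  else 0
  crossing <- NA_real_
  if (!is.null(awareness_threshold)) {
    hit <- which(abs(amplitude) >= awareness_threshold)
    if (length(hit)) crossing <- tms[hit[1]]
  }
  structure(list(time = tms, amplitude = amplitude,
                 threshold_crossing = crossing, trend_rho = rho,
                 smoothing = smoothing,
                 awareness_threshold = awareness_threshold),
            class = "rp_trace")
}

#' @export
print.rp_trace <- function(x, ...) {
  cat(sprintf("<rp_trace> %d samples, final amplitude %.4g, trend rho = %.3f, crossing = %s ms\n",
              length(x$time), x$amplitude[length(x$amplitude)], x$trend_rho,
              if (is.na(x$threshold_crossing)) "none"
              else format(round(x$threshold_crossing))))
  invisible(x)
}
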