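#' Attentional gate in BA9 (correlation of external and internal input)
#'
#' The degree of correlation between the externally generated and internally
#' (ACC-) generated signals in BA9 decides which ACC pathway is engaged:
#' pathway (a), net disinhibition of the pyramidal layer (the CR->CB
#' interneuron chain collapsed to an effective excitatory boost), when the
#' signals are correlated; pathway (b), direct drive of the inhibitory
#' interneurons suppressing the pyramidal layer, when they are not.
#' The statistic is the Pearson correlation of the two signals over the
#' window; with `band` set, each signal is band-passed (zero-phase FIR) and
#' its Hilbert amplitude envelope is correlated instead. The boundary case
#' `correlation == threshold` resolves to pathway (a).
#'
#' @param external,internal Equal-length numeric vectors or [avol_ts()]
#'   channels.
#' @param threshold Gate threshold on the correlation (default 0.3).
#' @param fs Sampling rate, Hz (needed when `band` is set).
#' @param band Optional two-element Hz interval for envelope correlation;
#'   `NULL` correlates the raw signals.
#' @return An object of class `gate_decision`: `correlation`, `pathway`
#'   (`"a_disinhibit"` or `"b_suppress"`), `threshold`.
#' @export
ba9_gate <- function(external, internal, threshold = 0.3, fs = NULL,
                     band = NULL) {
  if (inherits(external, "avol_ts")) {
    if (is.null(fs)) fs <- external$fs
    external <- ts_channel(external)
  }
  if (inherits(internal, "avol_ts")) internal <- ts_channel(internal)
  stopifnot(length(external) == length(internal), length(external) >= 10)
  if (sd(external) == 0 || sd(internal) == 0)
    stop("zero-variance gate input: correlation undefined")
  if (!is.null(band)) {
    stopifnot(!is.null(fs))
    external <- Mod(analytic_signal(bandpass(external, fs, band)))
    internal <- Mod(analytic_signal(bandpass(internal, fs, band)))
    if (sd(external) == 0 || sd(internal) == 0)
      stop("zero-variance envelope: correlation undefined")
  }
  r <- cor(external, internal)
  # boundary resolves to pathway (a); small tolerance so an exact tie is
  # not lost to floating-point rounding
  path <- if (r >= threshold - 1e-9) "a_disinhibit" else "b_suppress"
  structure(list(correlation = r, pathway = path, threshold = threshold),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("BA9 gate: r = %.3f (threshold %.2f) -> %s\n",
              x$correlation, x$threshold, x$pathway))
  invisible(x)
}

#' Deliberate versus arbitrary pathway
#'
#' Pathway (a) (disinhibition) engages the ACC feedback loop with the LPFC
#' subregions: the deliberate, endogenously driven mode with the full set of
#' protocol iterations. Pathway (b) suppresses ACC propagation: the
#' arbitrary, externally triggered mode, a single feed-forward pass.
#'
#' @param gate A `gate_decision` from [ba9_gate()].
#' @return `"deliberate"` or `"arbitrary"`.
#' @export
classify_pathway <- function(gate) {
  stopifnot(inherits(gate, "gate_decision"))
  if (gate$pathway == "a_disinhibit") "deliberate" else "arbitrary"
}

#' Theta carrier signal from ACC
#'
#' Band-passes the ACC excitatory mean to the carrier band (default theta,
#' 4-8 Hz) and packages it as an internal stimulus onto the given excitatory
#' targets. The window must cover at least three cycles of the band's low
#' edge.
#'
#' @param acc_ts [avol_ts()] holding the simulated ACC excitatory mean
#'   (first channel used).
#' @param band Carrier band, Hz.
#' @param targets Excitatory-layer unit indices the carrier should drive.
#' @param gain Scale applied to the filtered signal.
#' @return A [stimulus_spec()] (label `"internal"`) whose waveform
#'   interpolates the filtered carrier over the source window and is zero
#'   outside it; the filtered series is attached as attribute `"carrier"`.
#' @export
carrier_signal <- function(acc_ts, band = c(4, 8), targets, gain = 1) {
  stopifnot(inherits(acc_ts, "avol_ts"))
  x <- ts_channel(acc_ts)
  fs <- acc_ts$fs
  if (length(x) / fs < 3 / band[1])
    stop("window shorter than 3 cycles of the carrier band low edge")
  xf <- bandpass(x - mean(x), fs, band)
  tms <- ts_time(acc_ts)
  wf <- stats::approxfun(tms, gain * xf, yleft = 0, yright = 0)
  out <- stimulus_spec(targets, wf, label = "internal",
                       onset = tms[1], offset = tms[length(tms)])
  attr(out, "carrier") <- avol_ts(list(carrier = xf), fs = fs, t0 = tms[1])
  out
}

#' Salience competition among goal assemblies
#'
#' The ACC salience mechanism enhances assemblies whose activity is
#' phase-coupled to the theta carrier and suppresses the rest: each
#' assembly's signal is scored by phase-amplitude coupling ([pac_mvl()],
#' carrier phase vs assembly amplitude), and the scores compete through
#' their contrast against the mean score: assembly `k` receives the gain
#' multiplier `1 + boost * (s_k - mean(s)) / mean(s)` (clamped to
#' `[1 - suppress, 1 + boost]`), so above-average coupling is enhanced and
#' below-average coupling suppressed. Identical assemblies therefore all get
#' multiplier 1, and a (near-)silent carrier modulates nothing: all
#' multipliers are 1.
#'
#' @param assembly_signals Named list of numeric vectors (or an [avol_ts()]
#'   whose channels are the assembly signals).
#' @param carrier Numeric vector or [avol_ts()]: the carrier signal, same
#'   sampling as the assemblies.
#' @param fs Sampling rate, Hz.
#' @param phase_band,amp_band PAC bands, Hz.
#' @param boost,suppress Multiplier offsets for coupled / uncoupled
#'   assemblies.
#' @param n_surrogates,seed Passed to [pac_mvl()] (the surrogate p-values are
#'   reported in the attached PAC results).
#' @param carrier_tol Carrier SD (relative to mean assembly SD) below which
#'   the carrier counts as silent.
#' @return Named numeric vector of per-assembly gain multipliers, with the
#'   PAC results attached as attribute `"pac"`.
#' @export
salience_compete <- function(assembly_signals, carrier, fs = NULL,
                             phase_band = c(4, 8), amp_band = c(10, 80),
                             boost = 0.35, suppress = 0.35,
                             n_surrogates = 200, seed = 1L,
                             carrier_tol = 1e-3) {
  if (inherits(assembly_signals, "avol_ts")) {
    if (is.null(fs)) fs <- assembly_signals$fs
    assembly_signals <- assembly_signals$channels
  }
  if (inherits(carrier, "avol_ts")) carrier <- ts_channel(carrier)
  if (length(assembly_signals) == 0) stop("empty assembly list")
  stopifnot(!is.null(fs))
  nm <- names(assembly_signals)
  if (is.null(nm)) nm <- paste0("a", seq_along(assembly_signals))
  sds <- vapply(assembly_signals, sd, 0)
  if (sd(carrier) <= carrier_tol * max(mean(sds), 1e-12)) {
    out <- rep(1, length(assembly_signals))
    names(out) <- nm
    return(out)
  }
  pac <- lapply(assembly_signals, function(a)
    pac_mvl(carrier, a, fs = fs, phase_band = phase_band,
            amp_band = amp_band, n_surrogates = n_surrogates, seed = seed))
  s <- vapply(pac, function(p) p$mvl, 0)
  contrast <- (s - mean(s)) / max(mean(s), 1e-12)
  out <- clamp(1 + boost * contrast, 1 - suppress, 1 + boost)
  names(out) <- nm
  attr(out, "pac") <- pac
  out
}

#' ACC feedforward drive onto BA46
#'
#' Builds the simultaneous excitatory drive to BA46's excitatory and
#' feed-forward inhibitory layers that underlies the driven gamma regime:
#' the ACC signal (expectancy-weighted per action assembly) raises the
#' operating point of the fast excitatory/feed-forward-inhibitory loop, whose
#' balance of excitation and inhibition then oscillates in gamma. Excitatory
#' targets are weighted by the per-assembly expectancy vector; the
#' feed-forward inhibitory layer receives the same waveform scaled by
#' `ff_ratio`. With all expectancy weights zero both stimuli are identically
#' zero.
#'
#' @param acc_ts [avol_ts()] of the ACC excitatory mean.
#' @param ba46 The BA46 `network_state` (for assembly membership), or a
#'   `brain_model` together with `area = "BA46"`.
#' @param expectancy Numeric vector, one weight per BA46 assembly (>= 0).
#' @param scale Overall drive scale.
#' @param ff_ratio Feed-forward inhibitory drive as a fraction of the
#'   excitatory drive.
#' @param offset Constant (tonic) component added to the normalised ACC
#'   waveform, so the drive raises the operating point as well as carrying
#'   the ACC rhythm.
#' @param mod Depth of the ACC rhythm riding on the tonic component
#'   (fraction of `offset`).
#' @param unit_offset Offset added to unit indices (use the area's offset in
#'   a flattened brain).
#' @return List of two [stimulus_spec()]: `exc` (excitatory layer) and `ff`
#'   (feed-forward inhibitory layer; `NULL` when `ff_ratio = 0`).
#' @export
acc_ba46_feedforward <- function(acc_ts, ba46, expectancy, scale = 1,
                                 ff_ratio = 1, offset = 1, mod = 0.5,
                                 unit_offset = 0L) {
  stopifnot(inherits(acc_ts, "avol_ts"), inherits(ba46, "network_state"))
  if (length(ba46$assemblies) == 0) stop("BA46 has no assemblies")
  stopifnot(length(expectancy) == length(ba46$assemblies),
            all(expectancy >= 0))
  x <- ts_channel(acc_ts)
  s <- sd(x)
  xn <- if (s > 0) (x - mean(x)) / (2 * s) else rep(0, length(x))
  tms <- ts_time(acc_ts)
  if (all(expectancy == 0) || scale == 0) {
    zero <- function(t) rep(0, length(t))
    exc <- stimulus_spec(unlist(ba46$assemblies) + unit_offset, zero,
                         label = "internal")
    return(list(exc = exc, ff = NULL))
  }
  wf <- stats::approxfun(tms, scale * pmax(offset + mod * xn, 0),
                         yleft = 0, yright = 0)
  targets <- unlist(ba46$assemblies)
  wts <- rep(expectancy, lengths(ba46$assemblies))
  exc <- stimulus_spec(targets + unit_offset, wf, label = "internal",
                       onset = tms[1], offset = tms[length(tms)],
                       weights = wts)
  ff <- NULL
  if (ff_ratio > 0) {
    ff <- stimulus_spec(ba46$idx_ff + unit_offset, wf, label = "internal",
                        onset = tms[1], offset = tms[length(tms)],
                        weights = ff_ratio * mean(expectancy))
    attr(ff, "ff_ok") <- TRUE
  }
  list(exc = exc, ff = ff)
}
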