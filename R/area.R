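#' Parameters of one three-layer cortical area
#'
#' Each modelled area lumps the six cortical layers into three: a middle
#' excitatory layer of `n_exc` pyramidal units flanked by `n_ff_inh`
#' feed-forward inhibitory units above and `n_fb_inh` feedback inhibitory
#' units below. Excitatory units connect extensively among themselves
#' (strength decaying with grid distance, out to `ee_radius`), excitatory and
#' inhibitory units connect only locally (within `ei_radius`), there are no
#' inhibitory-inhibitory connections, and afferents from other areas contact
#' only the excitatory layer (or, for feed-forward inhibition, the
#' feed-forward inhibitory layer).
#'
#' The characteristic rhythm of an area is set by its two inhibitory loops:
#' the feedback loop (time constant `tau_fb`, conduction delay `d_fb`)
#' produces the slow baseline rhythm, while the faster feed-forward loop
#' (`tau_ff`, `d_ff`) produces gamma when the feed-forward layer is driven by
#' afferent input. Time constants and delays are in ms; delays must be integer
#' multiples of the integration step used later.
#'
#' Excitatory units sit on a square grid (10 x 10 for the default 100), each
#' inhibitory layer on a coarser grid covering the same extent. The excitatory
#' grid can be partitioned into `n_assemblies` square blocks representing
#' goal/action cell assemblies; `assembly_tau_scale` scales the membrane time
#' constants of the units in each block, giving assemblies distinct intrinsic
#' frequencies (modelling cytoarchitectonic heterogeneity).
#'
#' @param name Area label.
#' @param n_exc,n_ff_inh,n_fb_inh Unit counts; `n_exc` and the inhibitory
#'   counts must be perfect squares (grid layout).
#' @param tau_exc,tau_ff,tau_fb Membrane time constants, ms.
#' @param gain_exc,gain_ff,gain_fb [gain_params()] per population.
#' @param noise_sd Noise intensity, potential units per sqrt(ms); realised as
#'   an independent Gaussian increment of SD `noise_sd * sqrt(dt)` per unit
#'   and step.
#' @param tonic_exc Tonic background drive to the excitatory layer
#'   (potential units/ms), modelling nonspecific afferent/arousal input;
#'   it sets the operating point at which the excitatory-inhibitory balance
#'   oscillates.
#' @param w_ee Peak excitatory-excitatory weight (at distance 0).
#' @param ee_decay Length scale (grid units) of the E-E distance decay.
#' @param ee_radius Cut-off radius (grid units) for E-E connections.
#' @param w_e_ff,w_ff_e,w_e_fb,w_fb_e Magnitudes of E->FFinh, FFinh->E,
#'   E->FBinh, FBinh->E weights (inhibitory outgoing weights are stored with
#'   negative sign).
#' @param ei_radius Cut-off radius (grid units) for E<->I connections.
#' @param d_ee,d_e_ff,d_ff_e,d_e_fb,d_fb_e Conduction delays, ms.
#' @param w_max Hebbian saturation bound for plastic (excitatory-source)
#'   weights.
#' @param eta Hebbian learning rate in `[0, 1]` (per ms; increments are scaled
#'   by the integration step).
#' @param weight_jitter Relative uniform jitter applied to initial weights
#'   (`w * U(1 - jitter, 1 + jitter)`), seeded in [build_area()].
#' @param tau_jitter Relative uniform jitter applied per unit to the
#'   membrane time constants, dispersing the units' natural frequencies
#'   (cellular heterogeneity; makes population rhythms imperfectly
#'   coherent).
#' @param n_assemblies Number of square assembly blocks (0, 1 or 4 for the
#'   default grid).
#' @param assembly_tau_scale Numeric vector of per-assembly scale factors for
#'   the membrane time constants (recycled to `n_assemblies`).
#' @return An object of class `area_params`.
#' @export
area_params <- function(name = "area",
                        n_exc = 100, n_ff_inh = 25, n_fb_inh = 25,
                        tau_exc = 10, tau_ff = 5, tau_fb = 40,
                        gain_exc = gain_params(), gain_ff = gain_params(),
                        gain_fb = gain_params(),
                        noise_sd = 0.02, tonic_exc = 0,
                        w_ee = 0.05, ee_decay = 2, ee_radius = 4,
                        w_e_ff = 0.12, w_ff_e = 0.25,
                        w_e_fb = 0.12, w_fb_e = 0.25,
                        ei_radius = 2.5,
                        d_ee = 1, d_e_ff = 2, d_ff_e = 2,
                        d_e_fb = 6, d_fb_e = 6,
                        w_max = 1, eta = 0,
                        weight_jitter = 0.1, tau_jitter = 0,
                        n_assemblies = 0,
                        assembly_tau_scale = 1) {
  p <- list(name = name, n_exc = n_exc, n_ff_inh = n_ff_inh,
            n_fb_inh = n_fb_inh, tau_exc = tau_exc, tau_ff = tau_ff,
            tau_fb = tau_fb, gain_exc = gain_exc, gain_ff = gain_ff,
            gain_fb = gain_fb, noise_sd = noise_sd, tonic_exc = tonic_exc,
            w_ee = w_ee,
            ee_decay = ee_decay, ee_radius = ee_radius, w_e_ff = w_e_ff,
            w_ff_e = w_ff_e, w_e_fb = w_e_fb, w_fb_e = w_fb_e,
            ei_radius = ei_radius, d_ee = d_ee, d_e_ff = d_e_ff,
            d_ff_e = d_ff_e, d_e_fb = d_e_fb, d_fb_e = d_fb_e,
            w_max = w_max, eta = eta, weight_jitter = weight_jitter,
            tau_jitter = tau_jitter,
            n_assemblies = n_assemblies,
            assembly_tau_scale = assembly_tau_scale)
  class(p) <- "area_params"
  validate_area_params(p)
  p
}

validate_area_params <- function(p) {
  stopifnot(inherits(p, "area_params"))
  for (f in c("tau_exc", "tau_ff", "tau_fb"))
    if (!is.numeric(p[[f]]) || any(p[[f]] <= 0))
      stop("time constant `", f, "` must be > 0")
  for (f in c("d_ee", "d_e_ff", "d_ff_e", "d_e_fb", "d_fb_e"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stop("delay `", f, "` must be >= 0")
  for (f in c("gain_exc", "gain_ff", "gain_fb"))
    if (!inherits(p[[f]], "gain_params"))
      stop("`", f, "` must be a gain_params object")
  if (p$eta < 0 || p$eta > 1) stop("`eta` must lie in [0, 1]")
  if (p$w_max <= 0) stop("`w_max` must be positive")
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (p$tonic_exc < 0) stop("`tonic_exc` must be >= 0")
  for (f in c("w_ee", "w_e_ff", "w_ff_e", "w_e_fb", "w_fb_e"))
    if (p[[f]] < 0)
      stop("`", f, "` is a magnitude and must be >= 0")
  for (f in c("n_exc", "n_ff_inh", "n_fb_inh")) {
    s <- sqrt(p[[f]])
    if (p[[f]] < 1 || s != floor(s))
      stop("`", f, "` must be a positive perfect square (grid layout)")
  }
  if (!p$n_assemblies %in% c(0, 1, 4))
    stop("`n_assemblies` must be 0, 1 or 4")
  invisible(p)
}

# unit grid positions: E on an s x s integer grid, inhibitory layers on a
# coarser grid spanning the same extent
grid_positions <- function(n, extent_side) {
  s <- sqrt(n)
  step <- extent_side / s
  xy <- expand.grid(x = (seq_len(s) - 0.5) * step + 0.5,
                    y = (seq_len(s) - 0.5) * step + 0.5)
  as.matrix(xy)
}

# quadrant id (1..4) of a position on a side x side extent
quadrant_of <- function(pos, side) {
  qx <- as.integer(pos[, 1] > 0.5 + side / 2)
  qy <- as.integer(pos[, 2] > 0.5 + side / 2)
  1L + qx + 2L * qy
}

#' Build the state of one cortical area
#'
#' Draws the initial connectivity for an [area_params()] specification:
#' distance-decayed excitatory-excitatory weights, local
#' excitatory-inhibitory coupling, no inhibitory-inhibitory connections, and
#' multiplicative weight jitter drawn deterministically from `seed`.
#' Membrane potentials start at 0 and the delay history buffer is allocated
#' lazily at the first integration call (when `dt` is known).
#'
#' @param p An [area_params()] object.
#' @param seed Integer seed for the weight jitter.
#' @return An object of class `network_state` with fields `u` (per-unit mean
#'   membrane potential), `con` (connection table: target `i`, source `j`,
#'   weight `w`, delay `d` in ms, `plastic` flag, per-connection `eta` and
#'   `wmax`), per-unit parameter vectors, unit `layer` labels, grid `pos`,
#'   and `assemblies` (list of excitatory-unit index vectors).
#' @export
build_area <- function(p, seed = 1L) {
  validate_area_params(p)
  side <- sqrt(p$n_exc)
  pos_e <- grid_positions(p$n_exc, side)
  pos_ff <- grid_positions(p$n_ff_inh, side)
  pos_fb <- grid_positions(p$n_fb_inh, side)
  n <- p$n_exc + p$n_ff_inh + p$n_fb_inh
  layer <- rep(c("E", "FF", "FB"), c(p$n_exc, p$n_ff_inh, p$n_fb_inh))
  pos <- rbind(pos_e, pos_ff, pos_fb)
  idx_e <- seq_len(p$n_exc)
  idx_ff <- p$n_exc + seq_len(p$n_ff_inh)
  idx_fb <- p$n_exc + p$n_ff_inh + seq_len(p$n_fb_inh)

  pair_block <- function(src, tgt, radius, exclude_self = FALSE) {
    d <- as.matrix(stats::dist(rbind(pos[src, , drop = FALSE],
                                     pos[tgt, , drop = FALSE])))
    d <- d[seq_along(src), length(src) + seq_along(tgt), drop = FALSE]
    keep <- which(d <= radius, arr.ind = TRUE)
    if (exclude_self) {
      same <- src[keep[, 1]] == tgt[keep[, 2]]
      keep <- keep[!same, , drop = FALSE]
    }
    list(j = src[keep[, 1]], i = tgt[keep[, 2]],
         dist = d[keep])
  }

  ee <- pair_block(idx_e, idx_e, p$ee_radius, exclude_self = TRUE)
  e_ff <- pair_block(idx_e, idx_ff, p$ei_radius)
  ff_e <- pair_block(idx_ff, idx_e, p$ei_radius)
  e_fb <- pair_block(idx_e, idx_fb, p$ei_radius)
  fb_e <- pair_block(idx_fb, idx_e, p$ei_radius)

  con <- data.frame(
    i = c(ee$i, e_ff$i, ff_e$i, e_fb$i, fb_e$i),
    j = c(ee$j, e_ff$j, ff_e$j, e_fb$j, fb_e$j),
    w = c(p$w_ee * exp(-ee$dist / p$ee_decay),
          rep(p$w_e_ff, length(e_ff$i)),
          rep(-p$w_ff_e, length(ff_e$i)),
          rep(p$w_e_fb, length(e_fb$i)),
          rep(-p$w_fb_e, length(fb_e$i))),
    d = c(rep(p$d_ee, length(ee$i)), rep(p$d_e_ff, length(e_ff$i)),
          rep(p$d_ff_e, length(ff_e$i)), rep(p$d_e_fb, length(e_fb$i)),
          rep(p$d_fb_e, length(fb_e$i))),
    class = rep(c("ee", "e_ff", "ff_e", "e_fb", "fb_e"),
                c(length(ee$i), length(e_ff$i), length(ff_e$i),
                  length(e_fb$i), length(fb_e$i))),
    stringsAsFactors = FALSE)
  # only excitatory-source intrinsic connections are plastic
  con$plastic <- con$class %in% c("ee")
  con$eta <- ifelse(con$plastic, p$eta, 0)
  con$wmax <- p$w_max

  if (p$weight_jitter > 0 && nrow(con) > 0) {
    rs <- local_rng(seed, {
      runif(nrow(con), 1 - p$weight_jitter, 1 + p$weight_jitter)
    })
    con$w <- con$w * rs
  }
  tau_scale_units <- if (p$tau_jitter > 0)
    local_rng(seed + 7L, runif(n, 1 - p$tau_jitter, 1 + p$tau_jitter))
  else rep(1, n)

  tau <- c(rep(p$tau_exc, p$n_exc), rep(p$tau_ff, p$n_ff_inh),
           rep(p$tau_fb, p$n_fb_inh))
  Q <- c(rep(p$gain_exc$Q, p$n_exc), rep(p$gain_ff$Q, p$n_ff_inh),
         rep(p$gain_fb$Q, p$n_fb_inh))
  Cc <- c(rep(p$gain_exc$C, p$n_exc), rep(p$gain_ff$C, p$n_ff_inh),
          rep(p$gain_fb$C, p$n_fb_inh))

  assemblies <- list()
  tau <- tau * tau_scale_units
  if (p$n_assemblies == 1) {
    assemblies <- list(idx_e)
  } else if (p$n_assemblies == 4) {
    q_e <- quadrant_of(pos_e, side)
    assemblies <- lapply(1:4, function(q) idx_e[q_e == q])
    scale <- rep_len(p$assembly_tau_scale, 4)
    q_all <- quadrant_of(pos, side)
    for (q in 1:4) {
      units <- which(q_all == q)
      tau[units] <- tau[units] * scale[q]
    }
  }

  state <- structure(list(
    params = p, n = n, layer = layer, pos = pos,
    idx_e = idx_e, idx_ff = idx_ff, idx_fb = idx_fb,
    assemblies = assemblies,
    con = con,
    u = rep(0, n), tau = tau, Q = Q, C = Cc,
    noise_sd = rep(p$noise_sd, n),
    tonic = c(rep(p$tonic_exc, p$n_exc), rep(0, p$n_ff_inh + p$n_fb_inh)),
    t = 0, gbuf = NULL, gpos = NULL, dt = NULL, seed = seed
  ), class = "network_state")
  validate_network_state(state)
  state
}

validate_network_state <- function(state) {
  con <- state$con
  inh <- state$layer[con$j] != "E"
  if (any(con$w[inh] > 0))
    stop("inhibitory outgoing weight must be <= 0")
  if (any(state$layer[con$i] != "E" & inh))
    stop("inhibitory-inhibitory connection found (forbidden)")
  if (any(con$w[!inh] < 0))
    stop("excitatory outgoing weight must be >= 0")
  if (any(!is.finite(state$u))) stop("non-finite membrane potential")
  invisible(state)
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> '%s': %d units (%d E, %d FF-inh, %d FB-inh), %d connections, t = %g ms\n",
              x$params$name, x$n, length(x$idx_e), length(x$idx_ff),
              length(x$idx_fb), nrow(x$con), x$t))
  invisible(x)
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
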