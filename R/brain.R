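#' Long-range projection between areas
#'
#' Cortico-cortical projections are excitatory (pyramidal axons); inhibition
#' is exerted only through the target area's local interneurons, so the only
#' allowed termination layers are the excitatory layer and the feed-forward
#' inhibitory layer (feed-forward inhibition). Projections are topographic:
#' each source excitatory unit contacts target units within `topo_radius`
#' grid units of its own grid position.
#'
#' @param source,target Area names.
#' @param target_layer `"excitatory"` or `"ff_inhibitory"`.
#' @param weight_scale Total afferent weight per source unit (split over its
#'   contacts); must be >= 0.
#' @param delay Conduction delay, ms.
#' @param topo_radius Topographic contact radius, grid units.
#' @param plastic Logical; Hebbian plasticity on this projection.
#' @param eta Learning rate used when `plastic` (per ms).
#' @return An object of class `projection`.
#' @export
projection <- function(source, target, target_layer = "excitatory",
                       weight_scale = 0.1, delay = 10, topo_radius = 1.6,
                       plastic = FALSE, eta = 0) {
  target_layer <- match.arg(target_layer, c("excitatory", "ff_inhibitory"))
  stopifnot(weight_scale >= 0, delay >= 0)
  structure(list(source = source, target = target,
                 target_layer = target_layer, weight_scale = weight_scale,
                 delay = delay, topo_radius = topo_radius,
                 plastic = plastic, eta = eta),
            class = "projection")
}

#' Default brain configuration
#'
#' Area parameters and projection list for the five-region model: ACC and
#' BA9 are slow areas whose feedback-inhibitory loop (long `tau_fb`, long
#' loop delay) resonates in theta; BA10 and BA46 are fast executive areas
#' whose feedback loop gives an alpha/beta baseline and whose feed-forward
#' inhibitory loop (short `tau_ff`, short delay) resonates in gamma once the
#' feed-forward layer is driven. BA10 and BA46 are partitioned into four
#' goal/action assemblies with heterogeneous membrane time constants, giving
#' each assembly a distinct intrinsic rhythm. preSMA is a passive readout
#' (readiness-potential accumulator), not a simulated network.
#'
#' ACC projects to all three LPFC subregions; BA9, BA10 and BA46 are pairwise
#' bidirectionally connected; BA10 and BA9 project to preSMA. Projections
#' terminate on excitatory layers except ACC to BA46, which also drives the
#' feed-forward inhibitory layer (feed-forward inhibition underlying the
#' driven gamma regime).
#'
#' @return Nested list with elements `areas` (named [area_params()] list plus
#'   a `preSMA` readout marker), `projections` (list of [projection()]) and
#'   scalar fields `presma_w_ba10`, `presma_w_ba9` (readout weights).
#' @export
default_brain_config <- function() {
  # per-connection weights are chosen so the summed input per target unit
  # (weight x mean contact count for the default grids) sits at the operating
  # point where the slow feedback loop resonates in theta (slow areas) and
  # the feed-forward loop crosses into gamma only under afferent drive (fast
  # areas); see the methods vignette for the loop-gain calibration
  slow <- function(name) area_params(
    name = name, tau_exc = 30, tau_ff = 6, tau_fb = 110,
    gain_exc = gain_params(Q = 5), gain_ff = gain_params(Q = 5),
    gain_fb = gain_params(Q = 5),
    noise_sd = 0.02, tonic_exc = 0.35,
    w_ee = 0.0029, ee_decay = 2, ee_radius = 4,
    w_e_ff = 0.0038, w_ff_e = 0.0031, w_e_fb = 0.0023, w_fb_e = 0.0525,
    ei_radius = 2.5,
    d_ee = 1, d_e_ff = 2, d_ff_e = 2, d_e_fb = 12, d_fb_e = 12,
    w_max = 0.0029, eta = 0)
  fast <- function(name, tau_scale) area_params(
    name = name, tau_exc = 9, tau_ff = 4, tau_fb = 40,
    gain_exc = gain_params(Q = 5), gain_ff = gain_params(Q = 5),
    gain_fb = gain_params(Q = 5),
    noise_sd = 0.012, tonic_exc = 0.8,
    w_ee = 0.0029, ee_decay = 2, ee_radius = 4,
    w_e_ff = 0.0231, w_ff_e = 0.0929, w_e_fb = 0.0022, w_fb_e = 0.0926,
    ei_radius = 2.5,
    d_ee = 1, d_e_ff = 2.5, d_ff_e = 2.5, d_e_fb = 5, d_fb_e = 5,
    w_max = 0.0035, eta = 2e-5,
    n_assemblies = 4, assembly_tau_scale = tau_scale)
  list(
    areas = list(
      ACC = slow("ACC"),
      BA9 = slow("BA9"),
      BA10 = fast("BA10", c(1.00, 0.85, 1.18, 0.72)),
      BA46 = fast("BA46", c(1.00, 0.85, 1.18, 0.72)),
      preSMA = list(name = "preSMA", readout = TRUE)
    ),
    projections = list(
      projection("ACC", "BA9", "excitatory", weight_scale = 0.10, delay = 10),
      projection("ACC", "BA10", "excitatory", weight_scale = 0.03, delay = 10),
      projection("ACC", "BA46", "excitatory", weight_scale = 0.02, delay = 10),
      projection("ACC", "BA46", "ff_inhibitory", weight_scale = 0.03,
                 delay = 10),
      projection("BA9", "BA10", "excitatory", weight_scale = 0.05, delay = 8,
                 topo_radius = 3, plastic = TRUE, eta = 5e-5),
      projection("BA10", "BA9", "excitatory", weight_scale = 0.03, delay = 8),
      projection("BA10", "BA46", "excitatory", weight_scale = 0.10, delay = 6,
                 topo_radius = 3, plastic = TRUE, eta = 5e-5),
      projection("BA46", "BA10", "excitatory", weight_scale = 0.03, delay = 6),
      projection("BA9", "BA46", "excitatory", weight_scale = 0.03, delay = 8),
      projection("BA46", "BA9", "excitatory", weight_scale = 0.03, delay = 8),
      projection("BA10", "preSMA", "excitatory", weight_scale = 1, delay = 10),
      projection("BA9", "preSMA", "excitatory", weight_scale = 0.6, delay = 10)
    ),
    presma_w_ba10 = 1,
    presma_w_ba9 = 0.6
  )
}

required_areas <- c("ACC", "BA9", "BA10", "BA46", "preSMA")

#' Build the five-area brain model
#'
#' Instantiates the areas of a configuration (see [default_brain_config()]),
#' validates the projection graph (all five regions present; preSMA has
#' afferents from both BA10 and BA9; projections terminate only on excitatory
#' or feed-forward inhibitory layers) and flattens everything into a single
#' simulatable network with global unit indexing. Deterministic given `seed`.
#'
#' @param config Configuration list as returned by [default_brain_config()];
#'   unknown top-level keys are an error.
#' @param seed Integer seed (weight jitter).
#' @return An object of class `brain_model`: `areas` (per-area
#'   `network_state` or readout marker), `projections`, `net` (flattened
#'   `network_state` over all simulated units, with `area_of` and per-area
#'   `offsets`), `config`, `seed`.
#' @export
build_brain <- function(config = default_brain_config(), seed = 1L) {
  known <- c("areas", "projections", "presma_w_ba10", "presma_w_ba9")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!setequal(names(config$areas), required_areas))
    stop("config must define exactly the areas ",
         paste(required_areas, collapse = ", "))
  sim_names <- setdiff(required_areas, "preSMA")
  areas <- list()
  for (a in sim_names) {
    pa <- config$areas[[a]]
    if (!inherits(pa, "area_params"))
      stop("area `", a, "` must be an area_params object")
    areas[[a]] <- build_area(pa, seed = seed + match(a, sim_names))
  }
  areas$preSMA <- config$areas$preSMA

  for (pr in config$projections) {
    stopifnot(inherits(pr, "projection"))
    if (!pr$source %in% sim_names)
      stop("projection source must be a simulated area: ", pr$source)
    if (!pr$target %in% required_areas)
      stop("unknown projection target: ", pr$target)
  }
  to_presma <- vapply(config$projections,
                      function(p) p$target == "preSMA", TRUE)
  presma_src <- vapply(config$projections[to_presma],
                       function(p) p$source, "")
  if (!all(c("BA10", "BA9") %in% presma_src))
    stop("preSMA must receive projections from both BA10 and BA9")

  # ---- flatten simulated areas into one global network ----
  offsets <- c(0, cumsum(vapply(areas[sim_names], function(a) a$n, 0)))
  names(offsets) <- c(sim_names, "end")
  n_tot <- offsets[["end"]]
  area_of <- rep(sim_names, vapply(areas[sim_names], function(a) a$n, 0))
  con_list <- lapply(sim_names, function(a) {
    cn <- areas[[a]]$con
    cn$i <- cn$i + offsets[[a]]
    cn$j <- cn$j + offsets[[a]]
    cn
  })

  proj_con <- list()
  for (pr in config$projections) {
    if (pr$target == "preSMA") next   # readout, not a simulated connection
    src <- areas[[pr$source]]
    tgt <- areas[[pr$target]]
    tgt_idx <- if (pr$target_layer == "excitatory") tgt$idx_e else tgt$idx_ff
    tgt_pos <- tgt$pos[tgt_idx, , drop = FALSE]
    src_pos <- src$pos[src$idx_e, , drop = FALSE]
    ii <- integer()
    jj <- integer()
    ww <- numeric()
    for (k in seq_along(src$idx_e)) {
      d <- sqrt(colSums((t(tgt_pos) - src_pos[k, ])^2))
      hit <- which(d <= pr$topo_radius)
      if (!length(hit)) hit <- which.min(d)
      ii <- c(ii, tgt_idx[hit] + offsets[[pr$target]])
      jj <- c(jj, rep(src$idx_e[k] + offsets[[pr$source]], length(hit)))
      ww <- c(ww, rep(pr$weight_scale / length(hit), length(hit)))
    }
    # Hebbian headroom is per contact: consolidation may strengthen a
    # projection by at most 50% of its initial weight
    proj_con[[length(proj_con) + 1L]] <- data.frame(
      i = ii, j = jj, w = ww, d = pr$delay,
      class = paste0("proj_", pr$source, "_", pr$target,
                     if (pr$target_layer == "ff_inhibitory") "_ff" else ""),
      plastic = pr$plastic, eta = if (pr$plastic) pr$eta else 0,
      wmax = ww * 1.2,
      stringsAsFactors = FALSE)
  }
  con <- do.call(rbind, c(con_list, proj_con))

  net <- structure(list(
    params = list(name = "brain"), n = n_tot,
    layer = unlist(lapply(areas[sim_names], function(a) a$layer),
                   use.names = FALSE),
    pos = do.call(rbind, lapply(areas[sim_names], function(a) a$pos)),
    idx_e = unlist(lapply(sim_names, function(a)
      areas[[a]]$idx_e + offsets[[a]]), use.names = FALSE),
    idx_ff = unlist(lapply(sim_names, function(a)
      areas[[a]]$idx_ff + offsets[[a]]), use.names = FALSE),
    idx_fb = unlist(lapply(sim_names, function(a)
      areas[[a]]$idx_fb + offsets[[a]]), use.names = FALSE),
    assemblies = list(),
    con = con,
    u = rep(0, n_tot),
    tau = unlist(lapply(areas[sim_names], function(a) a$tau),
                 use.names = FALSE),
    Q = unlist(lapply(areas[sim_names], function(a) a$Q), use.names = FALSE),
    C = unlist(lapply(areas[sim_names], function(a) a$C), use.names = FALSE),
    noise_sd = unlist(lapply(areas[sim_names], function(a) a$noise_sd),
                      use.names = FALSE),
    tonic = unlist(lapply(areas[sim_names], function(a) a$tonic),
                   use.names = FALSE),
    t = 0, gbuf = NULL, gpos = NULL, dt = NULL, seed = seed,
    area_of = area_of, offsets = offsets
  ), class = "network_state")
  validate_network_state(net)

  structure(list(areas = areas, projections = config$projections,
                 net = net, config = config, seed = seed),
            class = "brain_model")
}

#' @export
print.brain_model <- function(x, ...) {
  cat(sprintf("<brain_model> %d simulated units in %s + preSMA readout; %d projections\n",
              x$net$n,
              paste(setdiff(required_areas, "preSMA"), collapse = "/"),
              length(x$projections)))
  invisible(x)
}

#' Unit indices of an area (or one of its assemblies) in the flattened net
#'
#' @param brain A `brain_model`.
#' @param area Area name.
#' @param assembly Optional assembly number within the area.
#' @param layer `"E"`, `"FF"` or `"FB"`.
#' @return Integer vector of global unit indices.
#' @export
brain_units <- function(brain, area, assembly = NULL, layer = "E") {
  stopifnot(inherits(brain, "brain_model"), area %in% names(brain$areas))
  a <- brain$areas[[area]]
  if (!inherits(a, "network_state")) stop(area, " is a readout area")
  off <- brain$net$offsets[[area]]
  idx <- if (!is.null(assembly)) {
    if (assembly > length(a$assemblies)) stop("no such assembly")
    a$assemblies[[assembly]]
  } else switch(layer, E = a$idx_e, FF = a$idx_ff, FB = a$idx_fb)
  idx + off
}

#' Projection table
#'
#' The brain's projection list as a data frame (exportable as CSV).
#' @param brain A `brain_model`.
#' @return data.frame with one row per projection.
#' @export
projection_table <- function(brain) {
  stopifnot(inherits(brain, "brain_model"))
  do.call(rbind, lapply(brain$projections, function(p)
    data.frame(source = p$source, target = p$target,
               target_layer = p$target_layer,
               weight_scale = p$weight_scale, delay = p$delay,
               plastic = p$plastic, stringsAsFactors = FALSE)))
}
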