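#' Write a time series to CSV
#'
#' First column `time_ms`, one column per channel, header row.
#'
#' @param ts An [avol_ts()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "avol_ts"))
  data.table::fwrite(as.data.frame(ts), path)
  invisible(path)
}

#' Read a time series from CSV
#'
#' Expects the layout written by [write_timeseries()]: a `time_ms` (or first)
#' column with uniformly spaced times in ms and at least one channel column.
#' The sampling rate is inferred from the time column and validated; ragged
#' rows and non-uniform sampling are errors.
#'
#' @param path CSV file.
#' @param jitter_tol Maximum relative deviation of time steps from their
#'   median.
#' @return An [avol_ts()].
#' @export
read_timeseries <- function(path, jitter_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) > 1 && length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("parse error in ", path, ": ragged row at line ", bad)
  }
  dt <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(dt) == 0) stop("empty series: ", path, " has a header but no rows")
  if (ncol(dt) < 2) stop(path, ": need a time column and >= 1 channel")
  tcol <- if ("time_ms" %in% names(dt)) "time_ms" else names(dt)[1]
  tms <- dt[[tcol]]
  if (nrow(dt) < 2) stop(path, ": need >= 2 samples to infer sampling rate")
  steps <- diff(tms)
  med <- median(steps)
  if (med <= 0 || any(abs(steps - med) > jitter_tol * med))
    stop(path, ": non-uniform sampling (relative jitter above ", jitter_tol,
         ")")
  ch <- dt[setdiff(names(dt), tcol)]
  avol_ts(as.list(ch), fs = 1000 / med, t0 = tms[1],
          meta = list(source = path))
}

#' Load a protocol configuration from YAML
#'
#' Maps the YAML keys onto [protocol_config()] arguments; `brain_seed` picks
#' the brain-construction seed and an optional `projections` list (entries
#' with `source`, `target`, and optionally `target_layer`, `weight_scale`,
#' `delay`) overrides matching default projections. Unknown keys are errors,
#' protecting against silently ignored parameter names.
#'
#' @param path YAML file.
#' @return List with `protocol` (a `protocol_config`), `brain_config`,
#'   `brain_seed`.
#' @export
load_protocol_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(protocol_config))
  extra <- setdiff(names(raw), c(known, "brain_seed", "projections"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  bc <- default_brain_config()
  if (!is.null(raw$projections)) {
    for (ov in raw$projections) {
      if (is.null(ov$source) || is.null(ov$target))
        stop("projection override needs `source` and `target`")
      hit <- which(vapply(bc$projections, function(p)
        p$source == ov$source && p$target == ov$target &&
          (is.null(ov$target_layer) || p$target_layer == ov$target_layer),
        TRUE))
      if (!length(hit))
        stop("no default projection ", ov$source, " -> ", ov$target)
      for (h in hit) {
        if (!is.null(ov$weight_scale))
          bc$projections[[h]]$weight_scale <- ov$weight_scale
        if (!is.null(ov$delay)) bc$projections[[h]]$delay <- ov$delay
      }
    }
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$expectancy)) args$expectancy <- as.numeric(args$expectancy)
  if (!is.null(args$goal_freqs)) args$goal_freqs <- as.numeric(args$goal_freqs)
  if (!is.null(args$mult_range)) args$mult_range <- as.numeric(args$mult_range)
  if (!is.null(args$carrier_band))
    args$carrier_band <- as.numeric(args$carrier_band)
  list(protocol = do.call(protocol_config, args),
       brain_config = bc,
       brain_seed = if (is.null(raw$brain_seed)) 1L
                    else as.integer(raw$brain_seed))
}

#' Write a protocol result to a run directory
#'
#' Writes `signals_iterNN.csv` per iteration, `metrics.json` (per-iteration
#' metric table, gate, mode, final multipliers, seed) and `rp.csv`.
#'
#' @param result A `protocol_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol_result <- function(result, dir) {
  stopifnot(inherits(result, "protocol_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (it in seq_along(result$signals))
    write_timeseries(result$signals[[it]],
                     file.path(dir, sprintf("signals_iter%02d.csv", it)))
  data.table::fwrite(data.frame(time_ms = result$rp$time,
                                rp = result$rp$amplitude),
                     file.path(dir, "rp.csv"))
  meta <- list(
    mode = result$mode,
    gate = if (is.null(result$gate)) NULL else
      list(correlation = result$gate$correlation,
           threshold = result$gate$threshold,
           pathway = result$gate$pathway),
    multipliers = as.list(result$multipliers),
    rp_trend_rho = result$rp$trend_rho,
    rp_threshold_crossing_ms = result$rp$threshold_crossing,
    seed = result$config$seed,
    iterations = result$iterations)
  jsonlite::write_json(meta, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
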