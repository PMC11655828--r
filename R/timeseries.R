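#' Uniformly sampled multichannel time series
#'
#' Container for the model's EEG-like output and for analysis inputs: a set of
#' equal-length, uniformly sampled channels with a sampling rate and free-form
#' provenance metadata (seed, config hash, ...).
#'
#' @param channels Named list or data.frame of equal-length numeric vectors.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, ms (default 0).
#' @param meta Named list of provenance metadata.
#' @return An object of class `avol_ts`.
#' @export
avol_ts <- function(channels, fs, t0 = 0, meta = list()) {
  stopifnot(is.numeric(fs), length(fs) == 1L, is.finite(fs), fs > 0)
  channels <- as.list(channels)
  if (length(channels) == 0L) stop("at least one channel required")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named")
  n <- unique(vapply(channels, length, 1L))
  if (length(n) != 1L) stop("all channels must have equal length")
  if (n == 0L) stop("empty channels")
  for (ch in channels)
    if (!is.numeric(ch)) stop("channels must be numeric")
  structure(list(channels = lapply(channels, as.numeric), fs = fs, t0 = t0,
                 meta = meta),
            class = "avol_ts")
}

#' @export
print.avol_ts <- function(x, ...) {
  cat(sprintf("<avol_ts> %d channel(s) x %d samples @ %g Hz (%.1f ms)\n",
              length(x$channels), ts_length(x), x$fs,
              ts_length(x) / x$fs * 1000))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname avol_ts
#' @param x An `avol_ts`.
#' @export
ts_length <- function(x) length(x$channels[[1L]])

#' @rdname avol_ts
#' @export
ts_time <- function(x) x$t0 + (seq_len(ts_length(x)) - 1L) / x$fs * 1000

#' Extract one channel as a numeric vector
#' @param x An `avol_ts`.
#' @param channel Channel name or index (default first channel).
#' @return Numeric vector.
#' @export
ts_channel <- function(x, channel = 1L) {
  stopifnot(inherits(x, "avol_ts"))
  ch <- x$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  ch
}

#' @export
as.data.frame.avol_ts <- function(x, ...) {
  data.frame(time_ms = ts_time(x), x$channels, check.names = FALSE)
}
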