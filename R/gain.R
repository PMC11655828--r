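#' Gain-function parameters
#'
#' Parameters of the Freeman sigmoid input-output function: `Q` is the
#' arousal/excitability gain and `C` a scale constant; both are unitless and
#' must be positive.
#'
#' @param Q Positive real; arousal / excitability gain.
#' @param C Positive real; output scale.
#' @return An object of class `gain_params`.
#' @seealso [freeman_gain()]
#' @export
gain_params <- function(Q = 5, C = 1) {
  stopifnot(is.numeric(Q), length(Q) == 1L, is.finite(Q), Q > 0,
            is.numeric(C), length(C) == 1L, is.finite(C), C > 0)
  structure(list(Q = Q, C = C), class = "gain_params")
}

#' @export
print.gain_params <- function(x, ...) {
  cat(sprintf("Freeman gain: Q = %g, C = %g (asymptote C*Q = %g)\n",
              x$Q, x$C, x$C * x$Q))
  invisible(x)
}

#' Freeman sigmoid gain function
#'
#' The asymmetric sigmoid `g(u) = C * Q * (1 - exp(-exp(u) / Q))` mapping mean
#' membrane potential to output activity. It is strictly increasing in `u`,
#' tends to 0 as `u -> -Inf` and saturates at `C * Q` as `u -> +Inf`; the
#' asymmetry (steep rise, slow saturation) reflects the experimentally
#' measured population transfer function of cortical tissue, with `Q`
#' modelling arousal-dependent excitability.
#'
#' @param u Numeric vector of membrane potentials (must be finite).
#' @param p A [gain_params()] object, or `NULL` to pass `Q`,`C` directly.
#' @param Q,C Used when `p` is `NULL`.
#' @return Numeric vector of activities in `(0, C * Q)`.
#' @examples
#' freeman_gain(0, Q = 1, C = 1)       # 1 - exp(-1)
#' freeman_gain(c(-2, 0, 2), Q = 5)
#' @export
freeman_gain <- function(u, p = NULL, Q = 5, C = 1) {
  if (!is.null(p)) {
    stopifnot(inherits(p, "gain_params"))
    Q <- p$Q
    C <- p$C
  }
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("`u` must be finite numeric")
  C * Q * (1 - exp(-exp(u) / Q))
}
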