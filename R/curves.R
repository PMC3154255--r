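#' Duration-dependent transition probability curve
#'
#' A `curve_spec` holds per-cycle transition probabilities indexed by
#' time already spent in a state (cycle 1 = first cycle in state).  The
#' recovery curve gives the probability of leaving a major depressive
#' episode as a function of episode duration; the relapse curve gives
#' the probability of falling back into depression as a function of
#' time since recovery.  Both are non-increasing: recovery becomes less
#' likely as an episode drags on, and relapse risk fades with sustained
#' recovery.
#'
#' Beyond the curve's span the `tail_rule` applies: `"hold_last"`
#' continues the final per-cycle probability indefinitely,
#' `"zero"` sets the probability to zero.
#'
#' @param p Numeric vector of per-cycle probabilities in `[0, 1]`,
#'   indexed by time-in-state `1..length(p)`.
#' @param tail_rule `"hold_last"` (default) or `"zero"`.
#' @param monotone If `TRUE` (default) the sequence must be
#'   non-increasing.
#' @return Object of class `curve_spec`.
#' @export
curve_spec <- function(p, tail_rule = c("hold_last", "zero"),
                       monotone = TRUE) {
  tail_rule <- match.arg(tail_rule)
  p <- as.numeric(p)
  if (length(p) < 1L) stop("curve needs at least one cycle", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("curve probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (monotone && any(diff(p) > 1e-12)) {
    stop("curve must be non-increasing in time-in-state", call. = FALSE)
  }
  structure(
    list(span_cycles = length(p), p = p, tail_rule = tail_rule),
    class = "curve_spec"
  )
}

#' @export
print.curve_spec <- function(x, ...) {
  cat(sprintf("<curve_spec> %d cycles, p(1) = %.4f, p(%d) = %.4f, tail = %s\n",
              x$span_cycles, x$p[1], x$span_cycles, x$p[x$span_cycles],
              x$tail_rule))
  invisible(x)
}

#' Look up a curve probability by time-in-state
#'
#' @param curve A [curve_spec()].
#' @param k Time-in-state index (1-based); values beyond the span follow
#'   the curve's tail rule.  Vectorised.
#' @return Per-cycle probability at each `k`.
#' @export
curve_prob <- function(curve, k) {
  stopifnot(inherits(curve, "curve_spec"), all(k >= 1))
  idx <- pmin(k, curve$span_cycles)
  out <- curve$p[idx]
  if (curve$tail_rule == "zero") out[k > curve$span_cycles] <- 0
  out
}

#' Generate a synthetic probability-decay curve
#'
#' Produces a non-increasing curve of per-cycle probabilities over a
#' fixed span, as a stand-in for empirically estimated recovery and
#' relapse curves.  Two families are supported:
#' \describe{
#'   \item{exponential_decay}{`p(k) = p_initial * exp(-decay * (k - 1))`}
#'   \item{power_decay}{`p(k) = p_initial * k^(-decay)`}
#' }
#'
#' @param family `"exponential_decay"` or `"power_decay"`.
#' @param p_initial First-cycle probability, in `[0, 1]`.
#' @param decay Non-negative decay rate; `0` gives a constant curve.
#' @param span_cycles Curve span (default 26 cycles, i.e. two years of
#'   four-week cycles).
#' @param tail_rule Passed through to [curve_spec()].
#' @return A [curve_spec()].
#' @examples
#' rc <- gen_curve("exponential_decay", p_initial = 0.25, decay = 0.10)
#' curve_prob(rc, 1)   # 0.25
#' curve_prob(rc, 26)  # 0.25 * exp(-2.5)
#' @export
gen_curve <- function(family = c("exponential_decay", "power_decay"),
                      p_initial, decay, span_cycles = 26L,
                      tail_rule = "hold_last") {
  family <- match.arg(family)
  if (!is.finite(p_initial) || p_initial < 0 || p_initial > 1) {
    stop("`p_initial` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(decay) || decay < 0) {
    stop("`decay` must be non-negative", call. = FALSE)
  }
  if (span_cycles < 1) stop("`span_cycles` must be >= 1", call. = FALSE)
  k <- seq_len(span_cycles)
  p <- switch(family,
    exponential_decay = p_initial * exp(-decay * (k - 1)),
    power_decay       = p_initial * k^(-decay)
  )
  curve_spec(p, tail_rule = tail_rule)
}
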