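#' Convert an instantaneous rate to a per-interval probability
#'
#' Transition evidence is often reported on a different time base than the
#' model cycle (e.g. a 6-month recurrence risk feeding a 3-month cycle).
#' Under a constant-hazard assumption the probability of at least one event
#' over an interval of length `time` is `1 - exp(-rate * time)`.
#'
#' @param rate Non-negative event rate, in events per unit time.
#' @param time Positive interval length, in the same time unit.
#' @return Probability in `[0, 1)`.
#' @seealso [prob_to_rate()] for the inverse transformation.
#' @examples
#' rate_to_prob(prob_to_rate(0.16, 0.25), 0.25)  # round trip: 0.16
#' @export
rate_to_prob <- function(rate, time) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("`time` must be finite and > 0", call. = FALSE)
  }
  1 - exp(-rate * time)
}

#' Convert a per-interval probability to an instantaneous rate
#'
#' Inverse of [rate_to_prob()]: `rate = -log(1 - prob) / time`. A probability
#' of 1 has no finite rate and is rejected.
#'
#' @param prob Probability in `[0, 1)`.
#' @param time Positive interval length the probability refers to.
#' @return Event rate per unit time.
#' @examples
#' prob_to_rate(0.16, 0.25)  # -log(0.84) / 0.25
#' @export
prob_to_rate <- function(prob, time) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob >= 1)) {
    stop("`prob` must be in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("`time` must be finite and > 0", call. = FALSE)
  }
  -log(1 - prob) / time
}

#' Re-express a probability on a different time base
#'
#' Convenience wrapper composing [prob_to_rate()] and [rate_to_prob()]:
#' converts a probability referring to an interval of length `from` into the
#' equivalent constant-hazard probability over an interval of length `to`.
#'
#' @param prob Probability in `[0, 1)` over the `from` interval.
#' @param from,to Positive interval lengths in a common unit.
#' @return Probability over the `to` interval.
#' @export
rescale_prob <- function(prob, from, to) {
  rate_to_prob(prob_to_rate(prob, from), to)
}
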