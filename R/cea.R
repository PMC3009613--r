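#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes the cost and QALY differences of a comparator against a
#' reference strategy and their ratio (ICER) at full floating-point
#' precision. When the comparator is cheaper and at least as effective it is
#' labelled `"dominant"`; when it is costlier and no more effective,
#' `"dominated"` (with an infinite ICER if the QALY difference is exactly
#' zero); identical outcomes are `"equivalent"`.
#'
#' @param reference,comparator `strategy_outcome` objects from the same
#'   [model_settings()].
#' @return An object of class `incremental_result`: list with
#'   `delta_cost`, `delta_qaly`, `icer` (KRW per QALY, may be `Inf` or `NA`
#'   under dominance), `status` (`"icer"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`), and the two strategy labels.
#' @export
incremental_analysis <- function(reference, comparator) {
  stopifnot(inherits(reference, "strategy_outcome"),
            inherits(comparator, "strategy_outcome"))
  dc <- comparator$cost - reference$cost
  dq <- comparator$qaly - reference$qaly
  if (dc == 0 && dq == 0) {
    status <- "equivalent"; icer <- NA_real_
  } else if (dq >= 0 && dc <= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (dq <= 0 && dc >= 0) {
    status <- "dominated"
    icer <- if (dq == 0) Inf else NA_real_
  } else {
    status <- "icer"; icer <- dc / dq
  }
  structure(
    list(reference = reference$strategy, comparator = comparator$strategy,
         delta_cost = dc, delta_qaly = dq, icer = icer, status = status),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  delta cost: %.0f KRW, delta QALY: %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$status == "icer") {
    cat(sprintf("  ICER: %.0f KRW/QALY\n", x$icer))
  } else {
    cat(sprintf("  %s\n", x$status))
  }
  invisible(x)
}

#' Net monetary benefit of a strategy outcome
#'
#' `lambda * QALY - cost`: converts effectiveness into money at the
#' willingness-to-pay threshold so strategies can be compared on one scale.
#'
#' @param outcome A `strategy_outcome` (or any list with `cost` and `qaly`).
#' @param lambda Willingness-to-pay threshold, KRW per QALY (>= 0).
#' @return KRW per person.
#' @export
net_monetary_benefit <- function(outcome, lambda) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  lambda * outcome$qaly - outcome$cost
}
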