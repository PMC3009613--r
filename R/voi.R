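#' Per-person expected value of perfect information
#'
#' EVPI at a willingness-to-pay threshold: the expected net monetary benefit
#' with perfect information (mean over draws of the per-draw best strategy)
#' minus the expected net benefit of the best strategy under current
#' information (best of the mean NMBs). Non-negative by construction.
#'
#' @param samples A `psa_samples` data frame from [run_psa()].
#' @param lambda Willingness-to-pay threshold, KRW per QALY.
#' @return EVPI in KRW per person.
#' @export
evpi_at_threshold <- function(samples, lambda) {
  if (nrow(samples) == 0) stop("no PSA samples", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  nmb_uc <- lambda * samples$qaly_uc - samples$cost_uc
  nmb_co <- lambda * samples$qaly_collab - samples$cost_collab
  mean(pmax(nmb_uc, nmb_co)) - max(mean(nmb_uc), mean(nmb_co))
}

#' Scale per-person EVPI to the affected population
#'
#' Annual incident cohorts over the decision horizon are discounted back to
#' present value; the default timing places each cohort at the start of its
#' year (year 0 undiscounted), so the multiplier is
#' `incidence * sum_{t=0}^{horizon-1} (1 + r)^-t`. Set
#' `cohort_timing = "end"` to discount every cohort one extra year.
#'
#' @param evpi_per_person KRW per person, from [evpi_at_threshold()].
#' @param annual_incidence New cases per year (base case: 57,400).
#' @param horizon_years Decision horizon in years (base case: 5).
#' @param discount_rate Annual discount rate (base case: 0.05).
#' @param cohort_timing `"start"` or `"end"` of year arrival.
#' @return Population EVPI in KRW.
#' @export
population_evpi <- function(evpi_per_person, annual_incidence = 57400,
                            horizon_years = 5, discount_rate = 0.05,
                            cohort_timing = c("start", "end")) {
  cohort_timing <- match.arg(cohort_timing)
  vals <- c(evpi_per_person, annual_incidence, horizon_years, discount_rate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all inputs must be finite and >= 0", call. = FALSE)
  }
  t <- seq_len(horizon_years) - 1
  if (cohort_timing == "end") t <- t + 1
  evpi_per_person * annual_incidence * sum((1 + discount_rate)^(-t))
}

#' EVPI across a willingness-to-pay grid
#'
#' @param samples A `psa_samples` data frame from [run_psa()].
#' @param lambdas Willingness-to-pay grid, KRW per QALY.
#' @param annual_incidence,horizon_years,discount_rate,cohort_timing Passed
#'   to [population_evpi()].
#' @return A data frame of class `evpi_curve`: `lambda`, `evpi_per_person`,
#'   `population_evpi`.
#' @export
evpi_curve <- function(samples, lambdas, annual_incidence = 57400,
                       horizon_years = 5, discount_rate = 0.05,
                       cohort_timing = "start") {
  if (length(lambdas) == 0) stop("empty lambda grid", call. = FALSE)
  evpi <- vapply(lambdas, function(l) evpi_at_threshold(samples, l), numeric(1))
  pop <- vapply(evpi, population_evpi, numeric(1),
                annual_incidence = annual_incidence,
                horizon_years = horizon_years,
                discount_rate = discount_rate,
                cohort_timing = cohort_timing)
  structure(
    data.frame(lambda = as.numeric(lambdas),
               evpi_per_person = evpi,
               population_evpi = pop),
    class = c("evpi_curve", "data.frame")
  )
}
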