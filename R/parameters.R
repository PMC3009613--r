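#' Strategy labels
#'
#' The model compares usual care alone against usual care plus acupuncture
#' delivered collaboratively in the same facility.
#' @format Character scalars.
#' @name strategies
NULL

#' @rdname strategies
#' @export
USUAL_CARE <- "usual_care"

#' @rdname strategies
#' @export
COLLABORATIVE <- "collaborative"

#' Transition parameters of the four-state model
#'
#' Quarterly transition probabilities of the chronic low back pain model:
#' acute patients either chronify (`tATC`) or recover (`tATW = 1 - tATC`)
#' after their single acute cycle; well patients relapse into chronic LBP
#' with probability `tWTC` per cycle; chronic patients under usual care
#' recover with probability `tCTW`; the collaborative strategy multiplies
#' `tCTW` by the pooled risk ratio `tRR`. All-cause mortality is a per-cycle
#' probability vector `mortality` (age-indexed when built from a life table).
#'
#' @param tATC Probability acute -> chronic per 3-month cycle.
#' @param tWTC Probability well -> chronic (recurrence) per cycle.
#' @param tCTW Probability chronic -> well under usual care per cycle.
#' @param tRR Risk ratio multiplying `tCTW` for the collaborative strategy.
#' @param mortality Per-cycle all-cause death probabilities; a scalar is
#'   recycled to `n_cycles`.
#' @param n_cycles Number of model cycles the mortality vector must cover.
#' @param rr_scale How the risk ratio is applied for the collaborative
#'   strategy: `"probability"` (default) multiplies `tCTW` directly (capped
#'   at 1); `"rate"` multiplies the equivalent constant hazard and converts
#'   back to a probability.
#' @return An object of class `transition_parameters` with fields `tATC`,
#'   `tATW`, `tWTC`, `tWTW`, `tCTW`, `tRR`, `mortality`, `rr_scale`.
#' @export
transition_parameters <- function(tATC = 0.24, tWTC = 0.16, tCTW = 0.35,
                                  tRR = 1.40, mortality = 0.001,
                                  n_cycles = 20L,
                                  rr_scale = c("probability", "rate")) {
  rr_scale <- match.arg(rr_scale)
  for (p in list(tATC = tATC, tWTC = tWTC, tCTW = tCTW)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("transition probabilities must be single values in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(tRR) || length(tRR) != 1L || !is.finite(tRR) || tRR <= 0) {
    stop("`tRR` must be a single positive number", call. = FALSE)
  }
  if (length(mortality) == 1L) mortality <- rep(mortality, n_cycles)
  if (length(mortality) < n_cycles) {
    stop(sprintf("mortality vector covers %d cycles but %d are required",
                 length(mortality), n_cycles), call. = FALSE)
  }
  if (any(!is.finite(mortality)) || any(mortality < 0) || any(mortality > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(tATC = tATC, tATW = 1 - tATC,
         tWTC = tWTC, tWTW = 1 - tWTC,
         tCTW = tCTW, tRR = tRR,
         mortality = as.numeric(mortality),
         rr_scale = rr_scale),
    class = "transition_parameters"
  )
}

#' Effective chronic-to-well probability for a strategy
#'
#' Usual care uses `tCTW` unchanged; the collaborative strategy applies the
#' risk ratio on the probability scale (`min(tRR * tCTW, 1)`, the default) or
#' on the hazard scale when `rr_scale = "rate"`. A clamped probability-scale
#' product raises a warning.
#'
#' @param params A [transition_parameters()] object.
#' @param strategy `USUAL_CARE` or `COLLABORATIVE`.
#' @return Recovery probability in `[0, 1]`.
#' @export
effective_tctw <- function(params, strategy) {
  stopifnot(inherits(params, "transition_parameters"))
  strategy <- match.arg(strategy, c(USUAL_CARE, COLLABORATIVE))
  if (strategy == USUAL_CARE) return(params$tCTW)
  if (params$rr_scale == "rate") {
    return(rate_to_prob(params$tRR * prob_to_rate(params$tCTW, 1), 1))
  }
  p <- params$tRR * params$tCTW
  if (p > 1) {
    warning(sprintf("tRR * tCTW = %.4f clamped to 1", p), call. = FALSE)
    p <- 1
  }
  p
}

#' Health-state utility weights
#'
#' Utilities on the 0 (dead) to 1 (full health) scale, per cycle of state
#' occupancy. Chronic LBP carries a strategy-specific utility because the
#' collaborative arm reports a slightly better chronic quality of life.
#' Independent PSA sampling may draw `uCLBPACUC < uCLBPUC`; this is allowed.
#'
#' @param uALBP Acute LBP utility.
#' @param uCLBPUC Chronic LBP utility under usual care.
#' @param uCLBPACUC Chronic LBP utility under collaborative treatment.
#' @param uWell Well-state utility.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(uALBP = 0.85, uCLBPUC = 0.62, uCLBPACUC = 0.65,
                        uWell = 0.96) {
  u <- list(uALBP = uALBP, uCLBPUC = uCLBPUC, uCLBPACUC = uCLBPACUC,
            uWell = uWell)
  for (nm in names(u)) {
    v <- u[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single utility in [0, 1]", nm), call. = FALSE)
    }
  }
  structure(u, class = "utility_set")
}

#' Default PSA distribution specifications
#'
#' The shipped base-case distributions: Beta for transition probabilities
#' and utilities, Gamma (shape, scale) for per-cycle chronic-state costs,
#' lognormal for the pooled risk ratio. Paired probabilities (`tATC`/`tATW`,
#' `tWTC`/`tWTW`) are represented by a single Beta draw whose complement
#' fills the partner, preserving row-stochasticity.
#'
#' @return Named list of [dist_spec()] objects with elements `tATC`, `tWTC`,
#'   `tCTW`, `uALBP`, `uCLBPUC`, `uCLBPACUC`, `uWell`, `cUC`, `cACUC`, `tRR`.
#' @export
default_dist_specs <- function() {
  list(
    tATC      = dist_spec("beta", 29, 91),
    tWTC      = dist_spec("beta", 26, 137),
    tCTW      = dist_spec("beta", 135, 252),
    uALBP     = dist_spec("beta", 3.97, 0.70),
    uCLBPUC   = dist_spec("beta", 13.99, 8.57),
    uCLBPACUC = dist_spec("beta", 14.14, 7.61),
    uWell     = dist_spec("beta", 22.08, 0.92),
    cUC       = dist_spec("gamma", 24.69, 20566.20),
    cACUC     = dist_spec("gamma", 19.54, 37372.18),
    tRR       = dist_spec("lognormal", 0.34, 0.05)
  )
}

#' Base-case point values of all sampled parameters
#'
#' @return Named numeric vector matching the names of [default_dist_specs()].
#' @export
default_point_values <- function() {
  c(tATC = 0.24, tWTC = 0.16, tCTW = 0.35,
    uALBP = 0.85, uCLBPUC = 0.62, uCLBPACUC = 0.65, uWell = 0.96,
    cUC = 507776, cACUC = 730329, tRR = 1.40)
}

# One joint draw from `specs` using the current RNG state. Draw order is
# fixed (transitions, utilities, costs, risk ratio) so seeds are portable.
draw_parameter_values <- function(specs) {
  order <- c("tATC", "tWTC", "tCTW",
             "uALBP", "uCLBPUC", "uCLBPACUC", "uWell",
             "cUC", "cACUC", "tRR")
  missing <- setdiff(order, names(specs))
  if (length(missing) > 0) {
    stop("missing distribution specs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vapply(specs[order], dist_sample, numeric(1))
}

#' Sample one joint parameter set for probabilistic sensitivity analysis
#'
#' Draws every uncertain input once, in a fixed documented order
#' (transitions, then utilities, then costs, then the risk ratio), seeds the
#' RNG, and assembles the domain objects. `tATW` and `tWTW` are set to the
#' complements of the sampled `tATC` and `tWTC`, so transition rows remain
#' stochastic for every draw.
#'
#' @param specs Named list of [dist_spec()] objects as in
#'   [default_dist_specs()].
#' @param seed Integer seed for reproducibility.
#' @param mortality,n_cycles Passed to [transition_parameters()].
#' @return A list with elements `transitions` ([transition_parameters()]),
#'   `utilities` ([utility_set()]), `chronic_costs` (named vector `cUC`,
#'   `cACUC`), and `values` (the raw named draw vector).
#' @export
sample_parameter_set <- function(specs = default_dist_specs(), seed,
                                 mortality = 0.001, n_cycles = 20L) {
  if (!missing(seed)) set.seed(seed)
  v <- draw_parameter_values(specs)
  list(
    transitions = transition_parameters(
      tATC = v[["tATC"]], tWTC = v[["tWTC"]], tCTW = v[["tCTW"]],
      tRR = v[["tRR"]], mortality = mortality, n_cycles = n_cycles),
    utilities = utility_set(
      uALBP = v[["uALBP"]], uCLBPUC = v[["uCLBPUC"]],
      uCLBPACUC = v[["uCLBPACUC"]], uWell = v[["uWell"]]),
    chronic_costs = c(cUC = v[["cUC"]], cACUC = v[["cACUC"]]),
    values = v
  )
}
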