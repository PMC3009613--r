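#' Probabilistic sensitivity analysis of the two-strategy model
#'
#' Draws `n_draws` joint parameter sets from the PSA distributions and runs
#' the full two-strategy cohort model once per draw. Within a draw the
#' transition probabilities and utilities for shared states are common to
#' both strategies; only the risk ratio, the chronic-state utility and the
#' chronic-state cycle cost are strategy-specific. Draws with a clamped
#' risk-ratio product (`tRR * tCTW > 1`) are kept, consistent with the
#' capped transition model.
#'
#' @param n_draws Number of Monte-Carlo iterations (base case: 10,000).
#' @param seed Integer seed; identical seeds give identical samples.
#' @param specs Named list of [dist_spec()] objects
#'   (default [default_dist_specs()]).
#' @param settings A [model_settings()] object.
#' @param mortality Per-cycle mortality (scalar or vector), as in
#'   [transition_parameters()].
#' @return A data frame of class `psa_samples` with one row per draw: the
#'   sampled parameter values, per-strategy `cost_uc`, `qaly_uc`,
#'   `cost_collab`, `qaly_collab`, and `delta_cost`, `delta_qaly`
#'   (collaborative minus usual care).
#' @export
run_psa <- function(n_draws = 10000L, seed = 1L,
                    specs = default_dist_specs(),
                    settings = model_settings(),
                    mortality = 0.001) {
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = 10,
                  dimnames = list(NULL, c("tATC", "tWTC", "tCTW",
                                          "uALBP", "uCLBPUC", "uCLBPACUC",
                                          "uWell", "cUC", "cACUC", "tRR")))
  for (i in seq_len(n_draws)) draws[i, ] <- draw_parameter_values(specs)

  out <- matrix(NA_real_, nrow = n_draws, ncol = 4,
                dimnames = list(NULL, c("cost_uc", "qaly_uc",
                                        "cost_collab", "qaly_collab")))
  for (i in seq_len(n_draws)) {
    v <- draws[i, ]
    params <- transition_parameters(
      tATC = v[["tATC"]], tWTC = v[["tWTC"]], tCTW = v[["tCTW"]],
      tRR = v[["tRR"]], mortality = mortality,
      n_cycles = settings$n_cycles)
    utils_i <- utility_set(v[["uALBP"]], v[["uCLBPUC"]],
                           v[["uCLBPACUC"]], v[["uWell"]])
    uc <- evaluate_strategy(USUAL_CARE, params, utils_i, v[["cUC"]], settings)
    co <- evaluate_strategy(COLLABORATIVE, params, utils_i, v[["cACUC"]], settings)
    out[i, ] <- c(uc$cost, uc$qaly, co$cost, co$qaly)
  }
  res <- data.frame(draw = seq_len(n_draws), draws, out)
  res$delta_cost <- res$cost_collab - res$cost_uc
  res$delta_qaly <- res$qaly_collab - res$qaly_uc
  class(res) <- c("psa_samples", "data.frame")
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' collaborative strategy is cost-effective is the fraction of PSA draws in
#' which its net monetary benefit strictly exceeds usual care's (ties count
#' toward the reference strategy). Under this pairwise definition the two
#' acceptance probabilities sum to one at every threshold.
#'
#' @param samples A `psa_samples` data frame from [run_psa()].
#' @param lambdas Willingness-to-pay grid, KRW per QALY.
#' @return A data frame of class `ceac_curve`: `lambda`, `p_collab`,
#'   `p_usual_care`.
#' @export
compute_ceac <- function(samples, lambdas) {
  if (nrow(samples) == 0) stop("no PSA samples", call. = FALSE)
  if (length(lambdas) == 0) stop("empty lambda grid", call. = FALSE)
  p <- vapply(lambdas, function(l) {
    mean(l * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  structure(
    data.frame(lambda = as.numeric(lambdas), p_collab = p, p_usual_care = 1 - p),
    class = c("ceac_curve", "data.frame")
  )
}

#' Threshold at which the acceptability curve crosses a level
#'
#' Returns the smallest grid threshold whose acceptance probability reaches
#' `level`, together with a linear interpolation between the bracketing grid
#' points. When the curve never reaches the level both values are `NA` and
#' `reached` is `FALSE`.
#'
#' @param curve A `ceac_curve` from [compute_ceac()].
#' @param level Probability level (default 0.5).
#' @return List with `grid_lambda`, `interpolated_lambda`, `reached`.
#' @export
ceac_crossing <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "ceac_curve"), level > 0, level <= 1)
  idx <- which(curve$p_collab >= level)
  if (length(idx) == 0) {
    return(list(grid_lambda = NA_real_, interpolated_lambda = NA_real_,
                reached = FALSE))
  }
  i <- idx[1]
  grid_lambda <- curve$lambda[i]
  if (i == 1L) {
    interp <- grid_lambda
  } else {
    p0 <- curve$p_collab[i - 1L]; p1 <- curve$p_collab[i]
    l0 <- curve$lambda[i - 1L]; l1 <- curve$lambda[i]
    interp <- if (p1 == p0) l1 else l0 + (level - p0) / (p1 - p0) * (l1 - l0)
  }
  list(grid_lambda = grid_lambda, interpolated_lambda = interp, reached = TRUE)
}
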