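#' Generate synthetic study-level recovery counts for meta-analysis
#'
#' Emulates the evidence base behind the pooled treatment effect: each study
#' draws its own log risk ratio from `Normal(true_log_rr, tau_between^2)`,
#' arm sizes uniformly from `arm_size_range`, control recoveries from
#' `Binomial(n, baseline_recovery_prob)` and treatment recoveries from
#' `Binomial(n, min(1, baseline * exp(study logRR)))`. A study whose implied
#' treatment probability exceeds 1 is redrawn (bounded retries) with a
#' warning.
#'
#' @param k Number of studies.
#' @param true_log_rr True underlying log risk ratio (base case 0.34).
#' @param tau_between Between-study SD of the log risk ratio.
#' @param arm_size_range Length-2 integer range of per-arm sizes.
#' @param baseline_recovery_prob Control-arm recovery probability per study
#'   period.
#' @param seed Integer seed.
#' @return Data frame with columns `study`, `events_t`, `total_t`,
#'   `events_c`, `total_c`.
#' @export
generate_meta_studies <- function(k = 50L, true_log_rr = 0.34,
                                  tau_between = 0.1,
                                  arm_size_range = c(200L, 500L),
                                  baseline_recovery_prob = 0.35,
                                  seed = 1L) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (baseline_recovery_prob <= 0 || baseline_recovery_prob >= 1) {
    stop("`baseline_recovery_prob` must be in (0, 1)", call. = FALSE)
  }
  if (tau_between < 0) stop("`tau_between` must be >= 0", call. = FALSE)
  set.seed(seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    p_t <- Inf
    for (try in 1:100) {
      study_lrr <- stats::rnorm(1, true_log_rr, tau_between)
      p_t <- baseline_recovery_prob * exp(study_lrr)
      if (p_t <= 1) break
      warning(sprintf("study %d implied recovery probability %.3f > 1; redrawn",
                      i, p_t), call. = FALSE)
    }
    if (p_t > 1) stop("could not draw a valid study effect", call. = FALSE)
    nt <- sample(arm_size_range[1]:arm_size_range[2], 1)
    nc <- sample(arm_size_range[1]:arm_size_range[2], 1)
    rows[[i]] <- data.frame(
      study = sprintf("synthetic_%02d", i),
      events_t = stats::rbinom(1, nt, p_t), total_t = nt,
      events_c = stats::rbinom(1, nc, baseline_recovery_prob), total_c = nc,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generate a synthetic life-table mortality schedule
#'
#' Stands in for the age- and sex-specific national life table the model's
#' mortality is meant to come from (values not otherwise available). Annual
#' mortality grows geometrically from `base_annual_mortality` at `start_age`
#' (a Gompertz-like progression); each annual probability is converted to a
#' per-quarter probability through the constant-hazard rate conversion, not
#' by division.
#'
#' @param start_age Age at model entry (base case: 60).
#' @param n_years Years covered (base case: 5).
#' @param base_annual_mortality Annual death probability at `start_age`
#'   (default 0.004, plausible for a 60-year-old woman; synthetic, not an
#'   official life-table value).
#' @param growth_per_year Relative annual increase of mortality (default 8%).
#' @return List of class `synthetic_life_table`: `annual` (data frame `age`,
#'   `q_annual`) and `per_cycle` (quarterly probabilities, 4 per year).
#' @export
generate_life_table <- function(start_age = 60L, n_years = 5L,
                                base_annual_mortality = 0.004,
                                growth_per_year = 0.08) {
  if (base_annual_mortality <= 0 || base_annual_mortality > 0.1) {
    stop("`base_annual_mortality` must be in (0, 0.1]", call. = FALSE)
  }
  if (growth_per_year < 0) stop("`growth_per_year` must be >= 0", call. = FALSE)
  if (n_years < 1) stop("`n_years` must be >= 1", call. = FALSE)
  age <- start_age + seq_len(n_years) - 1
  q_annual <- base_annual_mortality * (1 + growth_per_year)^(age - start_age)
  if (any(q_annual >= 1)) stop("annual mortality reached 1", call. = FALSE)
  q_quarter <- rate_to_prob(prob_to_rate(q_annual, 1), 0.25)
  if (any(q_quarter >= 1)) stop("quarterly mortality reached 1", call. = FALSE)
  structure(
    list(annual = data.frame(age = age, q_annual = q_annual),
         per_cycle = rep(q_quarter, each = 4L)),
    class = "synthetic_life_table"
  )
}

#' Write synthetic inputs to disk
#'
#' Writes `studies.csv` (per-arm recovery counts) and `life_table.csv`
#' (annual and per-cycle mortality) under `dir`, generated with the given
#' seed. Byte-identical across runs with the same arguments.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed for the study generator.
#' @param ... Passed on to [generate_meta_studies()].
#' @return Invisibly, the two file paths.
#' @export
write_synthetic_inputs <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  studies <- generate_meta_studies(seed = seed, ...)
  lt <- generate_life_table()
  f1 <- file.path(dir, "studies.csv")
  f2 <- file.path(dir, "life_table.csv")
  utils::write.csv(studies, f1, row.names = FALSE)
  lt_df <- data.frame(cycle = seq_along(lt$per_cycle) - 1L,
                      age = rep(lt$annual$age, each = 4L),
                      q_cycle = lt$per_cycle)
  utils::write.csv(lt_df, f2, row.names = FALSE)
  invisible(c(studies = f1, life_table = f2))
}
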