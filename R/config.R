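#' Path to the shipped base-case configuration
#'
#' @return Path to `default_config.yaml` inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "lbpcea",
              mustWork = TRUE)
}

config_allowed_keys <- list(
  top = c("model", "conventions", "transitions", "mortality", "utilities",
          "costs", "psa", "voi"),
  model = c("n_cycles", "cycle_length_years", "annual_discount_rate",
            "cohort_size"),
  conventions = c("reward_timing", "half_cycle", "cycle_discounting",
                  "rr_scale"),
  transitions = c("tATC", "tWTC", "tCTW", "tRR"),
  mortality = c("type", "per_cycle", "base_annual", "growth_per_year",
                "start_age", "values"),
  utilities = c("uALBP", "uCLBPUC", "uCLBPACUC", "uWell"),
  costs = c("usual_care", "collaborative", "indirect_nonmedical",
            "include_indirect"),
  strategy_costs = c("visits", "direct_nonmedical", "chronic_cycle_dist"),
  psa = c("n_draws", "seed", "lambda_grid"),
  voi = c("annual_incidence", "horizon_years", "discount_rate",
          "cohort_timing")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown key(s) in `%s`: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

check_prob_entry <- function(entry, name) {
  v <- entry$value
  if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
    stop(sprintf("`%s`: probability out of range [0, 1]", name), call. = FALSE)
  }
}

parse_dist_entry <- function(entry, name) {
  if (is.null(entry$dist)) {
    stop(sprintf("`%s`: missing `dist` family", name), call. = FALSE)
  }
  tryCatch(
    dist_spec(entry$dist, entry$a, if (is.null(entry$b)) 0 else entry$b),
    error = function(e) {
      stop(sprintf("`%s`: %s", name, conditionMessage(e)), call. = FALSE)
    }
  )
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML model configuration, rejects unknown keys, checks every
#' probability, rate and distribution, and returns a validated object. The
#' shipped default ([default_config_path()]) encodes the base case: 20
#' quarterly cycles, the published transition probabilities, utilities,
#' visit schedules and cost components, the PSA distributions, and the
#' accounting conventions under which the model reproduces the published
#' results.
#'
#' @param path Path to a YAML configuration (default: the shipped file).
#' @return A validated list of class `lbpcea_config`.
#' @export
load_config <- function(path = default_config_path()) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = "lbpcea_config", source = path)
}

#' Validate a configuration list
#'
#' @param cfg A configuration list (as read from YAML).
#' @return Invisibly `TRUE`; stops with a message naming the offending key
#'   otherwise.
#' @export
validate_config <- function(cfg) {
  check_keys(cfg, config_allowed_keys$top, "config")
  for (blk in config_allowed_keys$top) {
    if (is.null(cfg[[blk]])) stop(sprintf("missing `%s` block", blk), call. = FALSE)
  }
  check_keys(cfg$model, config_allowed_keys$model, "model")
  check_keys(cfg$conventions, config_allowed_keys$conventions, "conventions")
  check_keys(cfg$transitions, config_allowed_keys$transitions, "transitions")
  check_keys(cfg$mortality, config_allowed_keys$mortality, "mortality")
  check_keys(cfg$utilities, config_allowed_keys$utilities, "utilities")
  check_keys(cfg$costs, config_allowed_keys$costs, "costs")
  check_keys(cfg$psa, config_allowed_keys$psa, "psa")
  check_keys(cfg$voi, config_allowed_keys$voi, "voi")

  m <- cfg$model
  if (m$n_cycles < 1) stop("`model.n_cycles` must be >= 1", call. = FALSE)
  if (m$annual_discount_rate < 0 || m$annual_discount_rate >= 1) {
    stop("`model.annual_discount_rate` must be in [0, 1)", call. = FALSE)
  }
  if (m$cycle_length_years <= 0) {
    stop("`model.cycle_length_years` must be > 0", call. = FALSE)
  }
  if (!cfg$conventions$reward_timing %in% c("start", "end")) {
    stop("`conventions.reward_timing` must be start or end", call. = FALSE)
  }
  if (!cfg$conventions$rr_scale %in% c("probability", "rate")) {
    stop("`conventions.rr_scale` must be probability or rate", call. = FALSE)
  }
  for (nm in c("tATC", "tWTC", "tCTW")) {
    check_prob_entry(cfg$transitions[[nm]], paste0("transitions.", nm))
    parse_dist_entry(cfg$transitions[[nm]], paste0("transitions.", nm))
  }
  if (cfg$transitions$tRR$value <= 0) {
    stop("`transitions.tRR`: risk ratio must be > 0", call. = FALSE)
  }
  parse_dist_entry(cfg$transitions$tRR, "transitions.tRR")
  for (nm in config_allowed_keys$utilities) {
    check_prob_entry(cfg$utilities[[nm]], paste0("utilities.", nm))
    parse_dist_entry(cfg$utilities[[nm]], paste0("utilities.", nm))
  }
  if (!cfg$mortality$type %in% c("constant", "life_table", "vector")) {
    stop("`mortality.type` must be constant, life_table or vector", call. = FALSE)
  }
  for (strat in c("usual_care", "collaborative")) {
    blk <- cfg$costs[[strat]]
    check_keys(blk, config_allowed_keys$strategy_costs,
               paste0("costs.", strat))
    if (length(blk$visits) == 0) {
      stop(sprintf("`costs.%s.visits` is empty", strat), call. = FALSE)
    }
    parse_dist_entry(blk$chronic_cycle_dist,
                     paste0("costs.", strat, ".chronic_cycle_dist"))
    if (blk$direct_nonmedical < 0) {
      stop(sprintf("`costs.%s.direct_nonmedical` must be >= 0", strat),
           call. = FALSE)
    }
  }
  if (cfg$costs$indirect_nonmedical < 0) {
    stop("`costs.indirect_nonmedical` must be >= 0", call. = FALSE)
  }
  if (cfg$psa$n_draws < 1) stop("`psa.n_draws` must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Write a configuration back to YAML
#'
#' @param cfg An `lbpcea_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.lbpcea_config <- function(x, ...) {
  cat(sprintf("<lbpcea_config> %d cycles of %.2f years, discount %.0f%%\n",
              x$model$n_cycles, x$model$cycle_length_years,
              100 * x$model$annual_discount_rate))
  cat(sprintf("  conventions: reward %s, half-cycle %s, cycle discounting %s\n",
              x$conventions$reward_timing,
              x$conventions$half_cycle, x$conventions$cycle_discounting))
  invisible(x)
}

#' Model settings implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return A [model_settings()] object.
#' @export
config_settings <- function(cfg) {
  g <- cfg$psa$lambda_grid
  model_settings(
    n_cycles = cfg$model$n_cycles,
    cycle_length_years = cfg$model$cycle_length_years,
    annual_discount_rate = cfg$model$annual_discount_rate,
    cohort_size = cfg$model$cohort_size,
    reward_timing = cfg$conventions$reward_timing,
    half_cycle = cfg$conventions$half_cycle,
    cycle_discounting = cfg$conventions$cycle_discounting,
    lambda_grid = seq(g$from, g$to, by = g$by)
  )
}

#' Per-cycle mortality schedule implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return Numeric vector of per-cycle death probabilities (or a scalar for
#'   the constant type).
#' @export
config_mortality <- function(cfg) {
  m <- cfg$mortality
  switch(m$type,
    constant = m$per_cycle,
    vector = as.numeric(m$values),
    life_table = generate_life_table(
      start_age = if (is.null(m$start_age)) 60L else m$start_age,
      n_years = ceiling(cfg$model$n_cycles * cfg$model$cycle_length_years),
      base_annual_mortality = m$base_annual,
      growth_per_year = if (is.null(m$growth_per_year)) 0 else m$growth_per_year
    )$per_cycle
  )
}

#' Transition parameters implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return A [transition_parameters()] object at the point values.
#' @export
config_transitions <- function(cfg) {
  transition_parameters(
    tATC = cfg$transitions$tATC$value,
    tWTC = cfg$transitions$tWTC$value,
    tCTW = cfg$transitions$tCTW$value,
    tRR = cfg$transitions$tRR$value,
    mortality = config_mortality(cfg),
    n_cycles = cfg$model$n_cycles,
    rr_scale = cfg$conventions$rr_scale
  )
}

#' Utility set implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return A [utility_set()] at the point values.
#' @export
config_utilities <- function(cfg) {
  utility_set(
    uALBP = cfg$utilities$uALBP$value,
    uCLBPUC = cfg$utilities$uCLBPUC$value,
    uCLBPACUC = cfg$utilities$uCLBPACUC$value,
    uWell = cfg$utilities$uWell$value
  )
}

#' Per-cycle chronic-state costs implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @param strategy `USUAL_CARE` or `COLLABORATIVE`.
#' @param include_indirect Override of the config's `include_indirect` flag.
#' @return A [cycle_costs()] object built from the visit schedule and cost
#'   components.
#' @export
config_cycle_costs <- function(cfg, strategy,
                               include_indirect = cfg$costs$include_indirect) {
  blk <- cfg$costs[[strategy]]
  vs <- visit_schedule(
    vapply(blk$visits, `[[`, character(1), "label"),
    vapply(blk$visits, `[[`, numeric(1), "unit_cost"),
    vapply(blk$visits, `[[`, numeric(1), "frequency")
  )
  cycle_costs(visit_schedule_cost(vs), blk$direct_nonmedical,
              cfg$costs$indirect_nonmedical,
              include_indirect = include_indirect)
}

#' PSA distribution specifications implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return Named list of [dist_spec()] in the canonical sampling order.
#' @export
config_dist_specs <- function(cfg) {
  list(
    tATC = parse_dist_entry(cfg$transitions$tATC, "tATC"),
    tWTC = parse_dist_entry(cfg$transitions$tWTC, "tWTC"),
    tCTW = parse_dist_entry(cfg$transitions$tCTW, "tCTW"),
    uALBP = parse_dist_entry(cfg$utilities$uALBP, "uALBP"),
    uCLBPUC = parse_dist_entry(cfg$utilities$uCLBPUC, "uCLBPUC"),
    uCLBPACUC = parse_dist_entry(cfg$utilities$uCLBPACUC, "uCLBPACUC"),
    uWell = parse_dist_entry(cfg$utilities$uWell, "uWell"),
    cUC = parse_dist_entry(cfg$costs$usual_care$chronic_cycle_dist, "cUC"),
    cACUC = parse_dist_entry(cfg$costs$collaborative$chronic_cycle_dist, "cACUC"),
    tRR = parse_dist_entry(cfg$transitions$tRR, "tRR")
  )
}

#' Point values of all sampled parameters implied by a configuration
#'
#' @param cfg An `lbpcea_config`.
#' @return Named numeric vector (deterministic chronic-cycle costs are the
#'   component sums, base-case composition without indirect costs).
#' @export
config_point_values <- function(cfg) {
  c(tATC = cfg$transitions$tATC$value,
    tWTC = cfg$transitions$tWTC$value,
    tCTW = cfg$transitions$tCTW$value,
    uALBP = cfg$utilities$uALBP$value,
    uCLBPUC = cfg$utilities$uCLBPUC$value,
    uCLBPACUC = cfg$utilities$uCLBPACUC$value,
    uWell = cfg$utilities$uWell$value,
    cUC = cycle_cost_total(config_cycle_costs(cfg, USUAL_CARE,
                                              include_indirect = FALSE)),
    cACUC = cycle_cost_total(config_cycle_costs(cfg, COLLABORATIVE,
                                                include_indirect = FALSE)),
    tRR = cfg$transitions$tRR$value)
}

#' Deterministic base-case analysis
#'
#' Runs both strategies at the configuration's point values and returns the
#' per-strategy outcomes, the incremental comparison and the calibration
#' summary of the usual-care arm.
#'
#' @param cfg An `lbpcea_config` (default: shipped base case).
#' @param include_indirect Override the config's indirect-cost flag (the
#'   univariate sensitivity analysis re-runs the base case with `TRUE`).
#' @return List of class `base_case_result` with `usual_care`,
#'   `collaborative` (`strategy_outcome`s), `incremental`
#'   (`incremental_result`) and `validation` (see [validation_summary()]).
#' @export
run_base_case <- function(cfg = load_config(),
                          include_indirect = cfg$costs$include_indirect) {
  settings <- config_settings(cfg)
  params <- config_transitions(cfg)
  utilities <- config_utilities(cfg)
  uc <- evaluate_strategy(
    USUAL_CARE, params, utilities,
    cycle_cost_total(config_cycle_costs(cfg, USUAL_CARE, include_indirect)),
    settings)
  co <- evaluate_strategy(
    COLLABORATIVE, params, utilities,
    cycle_cost_total(config_cycle_costs(cfg, COLLABORATIVE, include_indirect)),
    settings)
  structure(
    list(usual_care = uc, collaborative = co,
         incremental = incremental_analysis(uc, co),
         validation = validation_summary(uc$trace, settings)),
    class = "base_case_result"
  )
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("Deterministic base case (per person)\n")
  cat(sprintf("  usual care:     %10.0f KRW  %6.4f QALY\n",
              x$usual_care$cost, x$usual_care$qaly))
  cat(sprintf("  collaborative:  %10.0f KRW  %6.4f QALY\n",
              x$collaborative$cost, x$collaborative$qaly))
  print(x$incremental)
  invisible(x)
}

#' Run the full analysis sequence and write all outputs
#'
#' Executes the complete pipeline on one configuration: deterministic base
#' case, univariate sensitivity analysis toggling indirect non-medical costs
#' on, probabilistic sensitivity analysis, acceptability curve, EVPI curve
#' and the calibration summary, writing `summary.json`, `trace.csv`,
#' `ce_plane.csv`, `ceac.csv`, `evpi.csv` and `manifest.json` under
#' `out_dir`. Fully reproducible from (config, seed).
#'
#' @param cfg An `lbpcea_config`.
#' @param out_dir Output directory (created if missing).
#' @param seed Override of `psa.seed` in the config.
#' @param n_draws Override of `psa.n_draws` in the config.
#' @return Invisibly, a list with all computed results.
#' @export
run_full_analysis <- function(cfg = load_config(), out_dir, seed = NULL,
                              n_draws = NULL) {
  stopifnot(inherits(cfg, "lbpcea_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(seed)) cfg$psa$seed else seed
  n_draws <- if (is.null(n_draws)) cfg$psa$n_draws else n_draws
  settings <- config_settings(cfg)

  base <- run_base_case(cfg)
  univariate <- run_base_case(cfg, include_indirect = TRUE)
  samples <- run_psa(n_draws = n_draws, seed = seed,
                     specs = config_dist_specs(cfg), settings = settings,
                     mortality = config_mortality(cfg))
  ceac <- compute_ceac(samples, settings$lambda_grid)
  crossing <- ceac_crossing(ceac, 0.5)
  evpi <- evpi_curve(samples, settings$lambda_grid,
                     annual_incidence = cfg$voi$annual_incidence,
                     horizon_years = cfg$voi$horizon_years,
                     discount_rate = cfg$voi$discount_rate,
                     cohort_timing = cfg$voi$cohort_timing)

  # trace.csv: long format, both strategies
  traces <- lapply(list(base$usual_care, base$collaborative), function(o) {
    tr <- o$trace
    data.frame(cycle = rep(as.integer(rownames(tr)), times = ncol(tr)),
               state = rep(colnames(tr), each = nrow(tr)),
               proportion = as.vector(tr),
               strategy = o$strategy)
  })
  utils::write.csv(do.call(rbind, traces), file.path(out_dir, "trace.csv"),
                   row.names = FALSE)
  utils::write.csv(samples[, c("draw", "delta_cost", "delta_qaly")],
                   file.path(out_dir, "ce_plane.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ceac), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(evpi), file.path(out_dir, "evpi.csv"),
                   row.names = FALSE)

  summary <- list(
    base_case = list(
      usual_care = list(cost = base$usual_care$cost,
                        qaly = base$usual_care$qaly),
      collaborative = list(cost = base$collaborative$cost,
                           qaly = base$collaborative$qaly),
      delta_cost = base$incremental$delta_cost,
      delta_qaly = base$incremental$delta_qaly,
      icer = base$incremental$icer,
      status = base$incremental$status
    ),
    univariate_indirect = list(
      delta_cost = univariate$incremental$delta_cost,
      delta_qaly = univariate$incremental$delta_qaly,
      icer = univariate$incremental$icer
    ),
    validation = base$validation,
    psa = list(
      n_draws = n_draws, seed = seed,
      p_collab_at_20m = ceac$p_collab[which.min(abs(ceac$lambda - 2e7))],
      ceac_crossing_50 = crossing
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "lbpcea",
    version = as.character(utils::packageVersion("lbpcea")),
    config = attr(cfg, "source"),
    config_md5 = unname(tools::md5sum(attr(cfg, "source"))),
    seed = seed, n_draws = n_draws,
    created = "run_full_analysis"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(base_case = base, univariate = univariate,
                 samples = samples, ceac = ceac, crossing = crossing,
                 evpi = evpi, summary = summary))
}
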