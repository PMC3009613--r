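# Brute-force path-enumeration oracle for the cohort engine: sums the
# probability of every state path of length `n_cycles` starting in ACUTE_LBP.
# Exponential in n_cycles; use only for tiny horizons.
enumerate_occupancy <- function(strategy, params, n_cycles) {
  occ <- matrix(0, nrow = n_cycles + 1, ncol = 4,
                dimnames = list(0:n_cycles, HEALTH_STATES))
  occ[1, 1] <- 1
  paths <- list(list(state = 1L, prob = 1))
  for (cyc in seq_len(n_cycles)) {
    m <- build_transition_matrix(strategy, params, cyc - 1L)
    nxt <- list()
    for (p in paths) {
      for (s in 1:4) {
        pr <- p$prob * m[p$state, s]
        if (pr > 0) nxt[[length(nxt) + 1]] <- list(state = s, prob = pr)
      }
    }
    paths <- nxt
    for (p in paths) occ[cyc + 1, p$state] <- occ[cyc + 1, p$state] + p$prob
  }
  occ
}

base_config <- function() load_config()

base_settings <- function(...) {
  args <- list(...)
  do.call(model_settings, args)
}

# Degenerate (point-mass) distribution specs at the base-case point values.
fixed_specs <- function(points = default_point_values()) {
  lapply(as.list(points), function(v) dist_spec("fixed", v))
}

# Small synthetic PSA sample table with known deltas, for CEAC/EVPI oracles.
fake_samples <- function(delta_cost, delta_qaly,
                         cost_uc = 0, qaly_uc = 0) {
  n <- length(delta_cost)
  data.frame(draw = seq_len(n),
             cost_uc = rep_len(cost_uc, n), qaly_uc = rep_len(qaly_uc, n),
             cost_collab = rep_len(cost_uc, n) + delta_cost,
             qaly_collab = rep_len(qaly_uc, n) + delta_qaly,
             delta_cost = delta_cost, delta_qaly = delta_qaly)
}
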