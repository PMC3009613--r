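base_params <- function(...) transition_parameters(...)

test_that("transition matrix reproduces the published structure", {
  p0 <- base_params(mortality = 0)
  m <- build_transition_matrix(USUAL_CARE, p0)
  expect_equal(unname(m["ACUTE_LBP", ]), c(0, 0.24, 0.76, 0))
  expect_equal(unname(m["CHRONIC_LBP", ]), c(0, 0.65, 0.35, 0))
  expect_equal(unname(m["WELL", ]), c(0, 0.16, 0.84, 0))
  expect_equal(unname(m["DEAD", ]), c(0, 0, 0, 1))

  mc <- build_transition_matrix(COLLABORATIVE, p0)
  expect_equal(mc["CHRONIC_LBP", "WELL"], 1.40 * 0.35)

  p1 <- base_params(mortality = 0.001)
  m1 <- build_transition_matrix(USUAL_CARE, p1)
  expect_equal(m1["ACUTE_LBP", "CHRONIC_LBP"], 0.999 * 0.24)
  expect_equal(unname(rowSums(m1)), rep(1, 4), tolerance = 1e-12)
})

test_that("rows stay stochastic for random parameter draws", {
  for (seed in 1:25) {
    s <- sample_parameter_set(seed = seed)
    for (strat in c(USUAL_CARE, COLLABORATIVE)) {
      m <- build_transition_matrix(strat, s$transitions)
      expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("risk ratio clamping warns and caps at 1", {
  p <- base_params(tCTW = 0.9, tRR = 1.40, mortality = 0)
  expect_warning(m <- build_transition_matrix(COLLABORATIVE, p), "clamped")
  expect_equal(m["CHRONIC_LBP", "WELL"], 1)
  expect_equal(unname(rowSums(m)), rep(1, 4))
})

test_that("rate-scale risk ratio application stays a valid probability", {
  p <- base_params(tCTW = 0.9, tRR = 1.40, mortality = 0, rr_scale = "rate")
  tctw <- effective_tctw(p, COLLABORATIVE)
  expect_true(tctw > 0.9 && tctw < 1)
  expect_equal(tctw, 1 - (1 - 0.9)^1.40, tolerance = 1e-12)
})

test_that("cohort engine matches the path-enumeration oracle", {
  # age-varying mortality exercises the per-cycle matrices
  p <- base_params(mortality = c(0.001, 0.002, 0.004, 0.008), n_cycles = 4L)
  s <- model_settings(n_cycles = 4L)
  for (strat in c(USUAL_CARE, COLLABORATIVE)) {
    trace <- run_cohort(strat, p, s)
    oracle <- enumerate_occupancy(strat, p, 4L)
    expect_equal(unclass(trace), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("cohort engine matches the matrix-power computation", {
  p <- base_params(mortality = 0.001)
  s <- model_settings()
  trace <- run_cohort(USUAL_CARE, p, s)
  m <- build_transition_matrix(USUAL_CARE, p)
  row <- c(1, 0, 0, 0)
  for (cyc in 1:20) {
    row <- row %*% m
    expect_equal(unname(trace[cyc + 1, ]), as.vector(row), tolerance = 1e-12)
  }
})

test_that("traces conserve the cohort and absorb deaths monotonically", {
  s <- model_settings()
  for (seed in 1:10) {
    draw <- sample_parameter_set(seed = seed)
    for (strat in c(USUAL_CARE, COLLABORATIVE)) {
      trace <- run_cohort(strat, draw$transitions, s)
      expect_equal(unname(rowSums(trace)), rep(1, 21), tolerance = 1e-10)
      expect_true(all(diff(trace[, "DEAD"]) >= -1e-15))
      expect_equal(unname(trace[1, ]), c(1, 0, 0, 0))
    }
  }
  immortal <- run_cohort(USUAL_CARE, base_params(mortality = 0), s)
  expect_true(all(immortal[, "DEAD"] == 0))
})

test_that("a fully chronic degenerate cohort stays put", {
  p <- base_params(tATC = 1, tCTW = 0, tRR = 1, mortality = 0)
  trace <- run_cohort(USUAL_CARE, p, model_settings())
  for (cyc in 2:21) {
    expect_equal(unname(trace[cyc, ]), c(0, 1, 0, 0))
  }
})

test_that("long-run chronic share matches the subchain eigenvector", {
  # with no deaths, the alive chronic/well chain has stationary chronic
  # share tWTC / (tWTC + tCTW)
  p <- base_params(mortality = 0, n_cycles = 200L)
  trace <- run_cohort(USUAL_CARE, p, model_settings(n_cycles = 200L))
  expect_equal(unname(trace[201, "CHRONIC_LBP"]), 0.16 / 0.51,
               tolerance = 1e-10)
  sub <- matrix(c(1 - 0.35, 0.35, 0.16, 1 - 0.16), nrow = 2, byrow = TRUE)
  ev <- eigen(t(sub))
  stat <- Re(ev$vectors[, which.max(Re(ev$values))])
  stat <- stat / sum(stat)
  expect_equal(stat[1], 0.16 / 0.51, tolerance = 1e-12)
})

test_that("collaborative care never accumulates more chronic person-cycles", {
  s <- model_settings()
  p <- base_params()
  uc <- run_cohort(USUAL_CARE, p, s)
  co <- run_cohort(COLLABORATIVE, p, s)
  expect_true(all(cumsum(co[, "CHRONIC_LBP"]) <=
                  cumsum(uc[, "CHRONIC_LBP"]) + 1e-14))
})

test_that("discount factors follow the annual rate on a quarterly grid", {
  s <- model_settings()
  expect_equal(discount_factor(0, s), 1)
  expect_equal(discount_factor(4, s), 1 / 1.05, tolerance = 1e-10)
  expect_equal(discount_factor(20, s), 1.05^-5, tolerance = 1e-10)
  expect_true(all(diff(discount_factor(0:20, s)) < 0))
})

test_that("reward accumulation matches closed forms on a degenerate trace", {
  # whole cohort well for every cycle
  n <- 20
  tr <- matrix(rep(c(0, 0, 1, 0), each = n + 1), nrow = n + 1,
               dimnames = list(0:n, HEALTH_STATES))
  tr[1, ] <- c(0, 0, 1, 0)
  trace <- structure(tr, strategy = USUAL_CARE,
                     class = c("cohort_trace", "matrix"))
  s <- model_settings(cycle_discounting = FALSE)
  out <- accumulate_outcomes(trace, utility_set(), 507776, s)
  expect_equal(out$qaly, 20 * 0.25 * 0.96)
  expect_equal(out$cost, 0)
})

test_that("per-cycle discounting reduces QALYs, equality only at rate zero", {
  p <- base_params()
  undisc <- evaluate_strategy(USUAL_CARE, p, utility_set(), 507776,
                              model_settings(cycle_discounting = FALSE))
  disc <- evaluate_strategy(USUAL_CARE, p, utility_set(), 507776,
                            model_settings(cycle_discounting = TRUE))
  zero <- evaluate_strategy(USUAL_CARE, p, utility_set(), 507776,
                            model_settings(cycle_discounting = TRUE,
                                           annual_discount_rate = 0))
  expect_lt(disc$qaly, undisc$qaly)
  expect_lt(disc$cost, undisc$cost)
  expect_equal(zero$qaly, undisc$qaly)
})

test_that("half-cycle correction averages start and end accumulation", {
  p <- base_params()
  u <- utility_set()
  start <- evaluate_strategy(USUAL_CARE, p, u, 507776,
                             model_settings(reward_timing = "start"))
  end <- evaluate_strategy(USUAL_CARE, p, u, 507776,
                           model_settings(reward_timing = "end"))
  half <- evaluate_strategy(USUAL_CARE, p, u, 507776,
                            model_settings(half_cycle = TRUE))
  expect_equal(half$qaly, (start$qaly + end$qaly) / 2, tolerance = 1e-12)
  expect_equal(half$cost, (start$cost + end$cost) / 2, tolerance = 1e-12)
})

test_that("validation summary counts chronic cases", {
  n <- 20
  tr <- matrix(rep(c(0, 0.3, 0.7, 0), each = n + 1), nrow = n + 1,
               dimnames = list(0:n, HEALTH_STATES))
  trace <- structure(tr, strategy = USUAL_CARE,
                     class = c("cohort_trace", "matrix"))
  v <- validation_summary(trace, model_settings())
  expect_equal(v$mean_chronic_cases, 3000)
  expect_equal(v$final_chronic_share, 0.3)
})

test_that("mortality schedule shorter than the horizon is rejected", {
  expect_error(transition_parameters(mortality = rep(0.001, 5), n_cycles = 20),
               "mortality")
  p <- base_params()
  expect_error(build_transition_matrix(USUAL_CARE, p, cycle = 25),
               "mortality schedule")
})
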