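studies_df <- function(et, nt, ec, nc) {
  data.frame(study = paste0("s", seq_along(et)),
             events_t = et, total_t = nt, events_c = ec, total_c = nc)
}

test_that("log risk ratios and standard errors match hand arithmetic", {
  same <- log_rr_and_se(studies_df(10, 100, 10, 100))
  expect_equal(same$log_rr, 0)
  two <- log_rr_and_se(studies_df(20, 100, 10, 100))
  expect_equal(two$log_rr, log(2), tolerance = 1e-12)
  expect_equal(two$se, sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100),
               tolerance = 1e-12)
  expect_equal(two$se, sqrt(0.13), tolerance = 1e-12)
})

test_that("zero cells get a continuity correction; empty studies are flagged", {
  zt <- log_rr_and_se(studies_df(0, 50, 8, 60))
  expect_true(zt$corrected)
  expect_true(is.finite(zt$log_rr) && is.finite(zt$se))
  expect_equal(zt$log_rr, log((0.5 / 51) / (8.5 / 61)), tolerance = 1e-12)
  none <- log_rr_and_se(studies_df(0, 50, 0, 60))
  expect_false(none$informative)
  expect_true(is.na(none$log_rr))
  expect_error(log_rr_and_se(studies_df(10, 0, 5, 50)), "positive")
  expect_error(log_rr_and_se(studies_df(60, 50, 5, 50)), "arm size")
})

test_that("pooling a single study returns it with zero heterogeneity", {
  one <- dersimonian_laird_pool(studies_df(20, 100, 10, 100))
  expect_equal(one$log_rr, log(2), tolerance = 1e-12)
  expect_equal(one$tau2, 0)
  expect_equal(one$k, 1)
})

test_that("identical studies pool to the common effect with SE / sqrt(k)", {
  k <- 4
  st <- studies_df(rep(20, k), rep(100, k), rep(10, k), rep(100, k))
  pooled <- dersimonian_laird_pool(st)
  single <- log_rr_and_se(studies_df(20, 100, 10, 100))
  expect_equal(pooled$log_rr, log(2), tolerance = 1e-12)
  expect_equal(pooled$tau2, 0)
  expect_equal(pooled$q, 0, tolerance = 1e-12)
  expect_equal(pooled$se, single$se / sqrt(k), tolerance = 1e-12)
})

test_that("pooled effect is permutation invariant and within study range", {
  st <- generate_meta_studies(k = 8, seed = 21)
  pooled <- dersimonian_laird_pool(st)
  shuffled <- dersimonian_laird_pool(st[sample(nrow(st)), ])
  expect_equal(pooled$log_rr, shuffled$log_rr, tolerance = 1e-12)
  expect_equal(pooled$tau2, shuffled$tau2, tolerance = 1e-12)
  yi <- log_rr_and_se(st)$log_rr
  expect_gte(pooled$log_rr, min(yi))
  expect_lte(pooled$log_rr, max(yi))
})

test_that("DerSimonian-Laird agrees with the metafor reference", {
  skip_if_not_installed("metafor")
  st <- log_rr_and_se(generate_meta_studies(k = 12, tau_between = 0.15,
                                            seed = 33))
  ours <- dersimonian_laird_pool(st)
  ref <- metafor::rma(yi = st$log_rr, sei = st$se, method = "DL")
  expect_equal(ours$log_rr, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("pooling recovers a planted treatment effect", {
  st <- generate_meta_studies(k = 50, true_log_rr = 0.34, tau_between = 0.1,
                              arm_size_range = c(200L, 500L), seed = 17)
  pooled <- dersimonian_laird_pool(st)
  expect_lt(abs(pooled$log_rr - 0.34), 3 * pooled$se)
})

test_that("a pooled effect converts to the PSA lognormal", {
  pooled <- structure(list(log_rr = 0.34, se = 0.05, tau2 = 0, q = 0, k = 6,
                           rr_point = exp(0.34)), class = "pooled_effect")
  spec <- pooled_to_lognormal(pooled)
  expect_equal(spec$family, "lognormal")
  expect_equal(spec$a, 0.34)
  expect_equal(spec$b, 0.05)
  expect_equal(exp(spec$a), 1.405, tolerance = 1e-3)
  # unit ratio maps to RR 1
  flat <- structure(list(log_rr = 0, se = 0.1, tau2 = 0, q = 0, k = 2,
                         rr_point = 1), class = "pooled_effect")
  expect_equal(dist_mean(pooled_to_lognormal(flat)), exp(0.005))
  # round trip through sampling: mean log draw recovers the pooled mean
  set.seed(1)
  draws <- dist_sample(spec, 1e5)
  expect_equal(mean(log(draws)), 0.34, tolerance = 0.002)
})
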