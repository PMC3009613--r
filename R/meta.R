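#' Log risk ratio and standard error of one two-arm study
#'
#' Computes `log[(eT/nT) / (eC/nC)]` and its large-sample standard error
#' `sqrt(1/eT - 1/nT + 1/eC - 1/nC)` from per-arm recovery counts. When a
#' study has any zero cell, 0.5 is added to all four cells (continuity
#' correction) before computing; a study with zero events in both arms is
#' flagged non-informative.
#'
#' @param studies Data frame with columns `study`, `events_t`, `total_t`,
#'   `events_c`, `total_c` (recoveries and arm sizes).
#' @return The input with added columns `log_rr`, `se`, `corrected`,
#'   `informative`.
#' @export
log_rr_and_se <- function(studies) {
  req <- c("events_t", "total_t", "events_c", "total_c")
  if (!all(req %in% names(studies))) {
    stop("`studies` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  with_df <- studies
  if (any(with_df$total_t <= 0) || any(with_df$total_c <= 0)) {
    stop("arm sizes must be positive", call. = FALSE)
  }
  if (any(with_df$events_t < 0) || any(with_df$events_c < 0) ||
      any(with_df$events_t > with_df$total_t) ||
      any(with_df$events_c > with_df$total_c)) {
    stop("events must lie in [0, arm size]", call. = FALSE)
  }
  et <- with_df$events_t; nt <- with_df$total_t
  ec <- with_df$events_c; nc <- with_df$total_c
  informative <- !(et == 0 & ec == 0)
  corrected <- (et == 0 | ec == 0 | et == nt | ec == nc) & informative
  et <- ifelse(corrected, et + 0.5, et)
  ec <- ifelse(corrected, ec + 0.5, ec)
  nt <- ifelse(corrected, nt + 1, nt)
  nc <- ifelse(corrected, nc + 1, nc)
  with_df$log_rr <- ifelse(informative, log((et / nt) / (ec / nc)), NA_real_)
  with_df$se <- ifelse(informative,
                       sqrt(1 / et - 1 / nt + 1 / ec - 1 / nc), NA_real_)
  with_df$corrected <- corrected
  with_df$informative <- informative
  with_df
}

#' DerSimonian-Laird random-effects pooling of log risk ratios
#'
#' Moment-based random-effects meta-analysis: fixed-effect inverse-variance
#' weights give Cochran's Q; the between-study variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`; the pooled
#' effect re-weights studies by `1 / (se^2 + tau2)`. With `tau2 = 0` the
#' estimate reduces exactly to the fixed-effect result, and a single study
#' is returned unchanged.
#'
#' @param studies Data frame of per-arm counts as in [log_rr_and_se()], or
#'   one already carrying `log_rr` and `se` columns.
#' @return An object of class `pooled_effect`: list with `log_rr`, `se`,
#'   `tau2`, `q`, `k`, `rr_point` (`exp(log_rr)`).
#' @export
dersimonian_laird_pool <- function(studies) {
  if (!all(c("log_rr", "se") %in% names(studies))) {
    studies <- log_rr_and_se(studies)
  }
  studies <- studies[!is.na(studies$log_rr) & !is.na(studies$se), , drop = FALSE]
  k <- nrow(studies)
  if (k == 0) stop("no informative studies to pool", call. = FALSE)
  y <- studies$log_rr
  w <- 1 / studies$se^2
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  tau2 <- if (k == 1) 0 else max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (studies$se^2 + tau2)
  log_rr <- sum(w_re * y) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  structure(
    list(log_rr = log_rr, se = se, tau2 = tau2, q = q, k = k,
         rr_point = exp(log_rr)),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("<pooled_effect> k = %d studies: RR %.3f (logRR %.4f, SE %.4f, tau2 %.4f)\n",
              x$k, x$rr_point, x$log_rr, x$se, x$tau2))
  invisible(x)
}

#' Convert a pooled effect into a lognormal PSA distribution
#'
#' The pooled log risk ratio and its standard error parameterise the
#' lognormal distribution sampled for the treatment effect in the PSA; the
#' point value is `exp(log_rr)`.
#'
#' @param pooled A `pooled_effect` from [dersimonian_laird_pool()].
#' @return A [dist_spec()] with family `"lognormal"`.
#' @export
pooled_to_lognormal <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_effect"))
  dist_spec("lognormal", pooled$log_rr, pooled$se)
}
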