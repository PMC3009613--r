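#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [compute_ceac()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  df <- rbind(
    data.frame(lambda = curve$lambda, p = curve$p_collab,
               strategy = "collaborative"),
    data.frame(lambda = curve$lambda, p = curve$p_usual_care,
               strategy = "usual care")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = lambda, y = p,
                                   colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (KRW per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot a population EVPI curve
#'
#' @param curve An `evpi_curve` from [evpi_curve()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_evpi <- function(curve) {
  stopifnot(inherits(curve, "evpi_curve"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = lambda, y = population_evpi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (KRW per QALY)",
                  y = "Population EVPI (KRW)")
}
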