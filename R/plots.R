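#' Plot a fitted concentration-response curve
#'
#' Well-level points and the fitted Hill curve on a log10
#' concentration axis.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    conc = 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = 200)
  )
  grid$inhibition <- hill_response(grid$conc, object$emax, object$log_ic50,
                                   object$hill_slope)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$inhibition)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                        color = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = "inhibition (%)",
                  title = sprintf("IC50 = %.2f µM", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Isobologram plot for one combination
#'
#' The additivity line joining the two solo IC50s, the combination
#' point, and (when it converged) the exponential connection curve.
#' Points below the line indicate synergy, above antagonism.
#'
#' @param object A `synergy_result` from [isobologram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synergy_result <- function(object, ...) {
  line <- tibble::tibble(
    x = c(object$drug_ic50, 0),
    y = c(0, object$modulator_ic50)
  )
  pt <- tibble::tibble(x = object$isobologram_point[1],
                       y = object$isobologram_point[2])
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_point(data = pt, color = "firebrick", size = 3) +
    ggplot2::labs(
      x = "drug (µM)", y = "modulator (µM)",
      title = sprintf("CI = %.2f (%s)", object$ci, object$interaction)
    ) +
    ggplot2::theme_minimal()
  if (isTRUE(object$curve_converged)) {
    cc <- object$connection_curve
    curve <- tibble::tibble(x = seq(0, object$drug_ic50, length.out = 200))
    curve$y <- (cc[["top"]] - cc[["bottom"]]) * exp(-cc[["k"]] * curve$x) +
      cc[["bottom"]]
    curve <- dplyr::filter(curve, .data$y >= 0)
    p <- p + ggplot2::geom_line(data = curve, color = "steelblue")
  }
  p
}

#' Combination-index overview plot
#'
#' CI per combination condition, faceted by schedule, with the
#' additivity band shaded.
#'
#' @param synergy A tibble from [synergy_table()] (or the `synergy`
#'   element of [analyze_plates()]).
#' @param additive_band Band half-width to shade.
#' @return A ggplot.
#' @export
plot_ci_overview <- function(synergy, additive_band = 0.05) {
  lab <- paste(synergy$modulator, synergy$modulator_conc_uM, sep = " ")
  d <- dplyr::mutate(synergy, condition = lab)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$ci,
                                  fill = .data$interaction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 1 - additive_band, ymax = 1 + additive_band,
                      alpha = 0.15) +
    ggplot2::facet_wrap(~schedule) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "combination index") +
    ggplot2::theme_minimal()
}
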