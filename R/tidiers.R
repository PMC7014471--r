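#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (NA when no curvature information is available, e.g.
#'   robust fits).
#' @export
tidy.hill_fit <- function(x, ...) {
  terms <- c("emax", "log_ic50", "hill_slope")
  se <- rep(NA_real_, 3)
  if (!is.null(x$vcov)) {
    present <- intersect(terms, rownames(x$vcov))
    se[match(present, terms)] <- sqrt(pmax(diag(x$vcov)[present], 0))
  }
  tibble::tibble(
    term = terms,
    estimate = c(x$emax, x$log_ic50, x$hill_slope),
    std.error = se
  )
}

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ic50`, `ic50_lower`, `ic50_upper`,
#'   `cl_method`, `emax`, `hill_slope`, `rss`, `n_points`, `converged`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    ic50 = x$ic50,
    ic50_lower = x$ic50_cl[["lower"]], ic50_upper = x$ic50_cl[["upper"]],
    cl_method = x$cl_method, emax = x$emax, hill_slope = x$hill_slope,
    rss = x$rss, n_points = x$n_points, converged = x$converged
  )
}

#' Tidy a synergy result
#'
#' @param x A `synergy_result`.
#' @param ... Unused.
#' @return A one-row tibble: the IC50 inputs, `rr`, `ci`,
#'   `interaction`, `point_side`.
#' @export
tidy.synergy_result <- function(x, ...) {
  tibble::tibble(
    schedule = x$schedule_id, drug_ic50 = x$drug_ic50,
    modulator_ic50 = x$modulator_ic50, combo_ic50 = x$combo_ic50,
    modulator_conc = x$modulator_conc,
    rr = x$rr, ci = x$ci, interaction = x$interaction,
    point_side = x$point_side
  )
}
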