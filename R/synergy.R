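#' Reversal ratio (cytotoxicity enhancement ratio)
#'
#' Fold reduction of a drug's IC50 caused by a co-administered
#' chemosensitizer: `ic50_drug_alone / ic50_combo`. Values > 1 indicate
#' potentiation.
#'
#' @param ic50_drug_alone,ic50_combo IC50 values in µM (vectorized);
#'   both must be > 0.
#' @return Dimensionless ratio(s).
#' @examples
#' reversal_ratio(14.4, 1.0) # 14.4-fold potentiation
#' @export
reversal_ratio <- function(ic50_drug_alone, ic50_combo) {
  if (any(!is.finite(ic50_drug_alone)) || any(!is.finite(ic50_combo)) ||
      any(ic50_drug_alone <= 0) || any(ic50_combo <= 0)) {
    abort("IC50 values must be positive and finite.")
  }
  ic50_drug_alone / ic50_combo
}

#' Combination index from IC50 values
#'
#' For a fixed-modulator design in which drug A is titrated in the
#' presence of modulator B held at concentration `c_b`, the Loewe-type
#' combination index at the 50% effect level is
#' \deqn{CI = C_{A,50}/IC_{50,A} + C_{B}/IC_{50,B}}
#' where `C_{A,50}` is the drug IC50 of the combination curve and the
#' denominators are the agents' solo IC50s. CI < 1 indicates synergy,
#' CI = 1 additivity, CI > 1 antagonism.
#'
#' @param combo_ic50 Drug IC50 of the combination curve (µM).
#' @param drug_ic50 Drug-alone IC50 (µM).
#' @param modulator_conc Fixed modulator concentration (µM).
#' @param modulator_ic50 Modulator-alone IC50 (µM).
#' @return Dimensionless CI value(s); vectorized.
#' @examples
#' ci_value(8.6, 14.4, 50, 197.0) # 0.85
#' @export
ci_value <- function(combo_ic50, drug_ic50, modulator_conc, modulator_ic50) {
  if (any(c(combo_ic50, drug_ic50, modulator_ic50) <= 0)) {
    abort("IC50 values must be > 0.")
  }
  if (any(modulator_conc < 0)) abort("`modulator_conc` must be >= 0.")
  combo_ic50 / drug_ic50 + modulator_conc / modulator_ic50
}

#' Build a combination experiment
#'
#' Bundles the three fits that define one fixed-modulator combination
#' at one schedule: the drug alone, the modulator alone (same
#' schedule), and the drug + fixed-modulator combination curve. The
#' modulator must be used at a sub-IC50 (chemosensitizing, around
#' IC10-IC20) concentration.
#'
#' @param drug_fit_alone,modulator_fit_alone,combo_fit Converged
#'   `hill_fit` objects (or bare IC50s in µM).
#' @param modulator_conc Fixed modulator concentration, µM, > 0 and
#'   below the modulator's own IC50.
#' @param schedule_id Exposure-schedule label.
#' @return An object of class `combination_experiment`.
#' @export
combination_experiment <- function(drug_fit_alone, modulator_fit_alone,
                                   modulator_conc, combo_fit,
                                   schedule_id = NA_character_) {
  as_ic50 <- function(x, what) {
    if (inherits(x, "hill_fit")) {
      if (!isTRUE(x$converged)) abort(paste(what, "fit has not converged."))
      x$ic50
    } else {
      as.numeric(x)
    }
  }
  ic_a <- as_ic50(drug_fit_alone, "drug-alone")
  ic_b <- as_ic50(modulator_fit_alone, "modulator-alone")
  c_a <- as_ic50(combo_fit, "combination")
  if (any(c(ic_a, ic_b, c_a) <= 0)) abort("IC50 values must be > 0.")
  if (modulator_conc <= 0) abort("`modulator_conc` must be > 0.")
  if (modulator_conc >= ic_b) {
    warn("modulator is not sub-IC50; chemosensitization designs use about IC10-IC20.")
  }
  structure(
    list(drug_ic50 = ic_a, modulator_ic50 = ic_b, combo_ic50 = c_a,
         modulator_conc = modulator_conc, schedule_id = schedule_id),
    class = "combination_experiment"
  )
}

#' Combination index of a combination experiment
#'
#' @param exp A [combination_experiment()].
#' @return Dimensionless CI (full precision; report rounded to 2
#'   decimals by convention).
#' @export
combination_index <- function(exp) {
  stopifnot(inherits(exp, "combination_experiment"))
  ci_value(exp$combo_ic50, exp$drug_ic50, exp$modulator_conc,
           exp$modulator_ic50)
}

#' Classify a drug-drug interaction from its combination index
#'
#' Synergistic when `ci < 1 - additive_band`, antagonistic when
#' `ci > 1 + additive_band`, additive otherwise. The default band of
#' 0.05 reflects that CI values within a few hundredths of 1 are not
#' distinguishable from additivity at plate-assay precision.
#'
#' @param ci Combination index value(s), > 0.
#' @param additive_band Half-width of the additivity band around 1.
#' @return Character vector: `"synergistic"`, `"additive"` or
#'   `"antagonistic"`.
#' @export
classify_interaction <- function(ci, additive_band = 0.05) {
  if (any(ci <= 0)) abort("`ci` must be > 0.")
  if (additive_band < 0) abort("`additive_band` must be >= 0.")
  dplyr::case_when(
    ci < 1 - additive_band ~ "synergistic",
    ci > 1 + additive_band ~ "antagonistic",
    .default = "additive"
  )
}

#' Side of the additivity line for a combination point
#'
#' The additivity locus of an isobologram is the segment joining
#' `(IC50_A, 0)` and `(0, IC50_B)`. A dose pair `(x, y)` lies below,
#' on, or above that line according to the sign of the normalized sum
#' `x/IC50_A + y/IC50_B - 1` (tolerance 1e-9 for "on"). This is exactly
#' the combination index minus one, so the geometric side test and the
#' CI classification agree case-for-case.
#'
#' @param point Numeric length-2: drug and modulator dose (µM).
#' @param line_endpoints List of two numeric length-2 points, the line
#'   ends `(IC50_A, 0)` and `(0, IC50_B)` (in either order).
#' @return `"below"`, `"on"` or `"above"`.
#' @export
point_side <- function(point, line_endpoints) {
  p1 <- line_endpoints[[1]]; p2 <- line_endpoints[[2]]
  if (isTRUE(all.equal(p1, p2))) abort("line endpoints must be distinct.")
  # identify the axis intercepts regardless of ordering
  ic_a <- max(p1[1], p2[1]); ic_b <- max(p1[2], p2[2])
  if (ic_a <= 0 || ic_b <= 0) abort("endpoints must lie on the positive axes.")
  s <- point[1] / ic_a + point[2] / ic_b - 1
  if (abs(s) <= 1e-9) "on" else if (s < 0) "below" else "above"
}

#' Isobologram geometry and synergy summary for one combination
#'
#' Computes the reversal ratio, combination index and interaction call
#' for a [combination_experiment()], together with the isobologram
#' geometry: the additivity line from `(IC50_A, 0)` to `(0, IC50_B)`,
#' the combination point `(C_A,50, C_B)`, its side of the line, and a
#' decorative exponential connection curve
#' `y = (top - bottom) exp(-k x) + bottom` least-squares fitted through
#' the two axis intercepts and the combination point (used only for
#' plotting; classification always uses the exact normalized-sum side
#' test). If the curve fit fails the geometry is returned without it
#' and flagged.
#'
#' @param exp A [combination_experiment()].
#' @param additive_band Half-width of the CI additivity band.
#' @return An object of class `synergy_result`.
#' @export
isobologram <- function(exp, additive_band = 0.05) {
  stopifnot(inherits(exp, "combination_experiment"))
  ci <- combination_index(exp)
  rr <- reversal_ratio(exp$drug_ic50, exp$combo_ic50)
  pt <- c(exp$combo_ic50, exp$modulator_conc)
  line <- list(c(exp$drug_ic50, 0), c(0, exp$modulator_ic50))
  side <- point_side(pt, line)
  curve <- fit_connection_curve(
    x = c(exp$drug_ic50, 0, exp$combo_ic50),
    y = c(0, exp$modulator_ic50, exp$modulator_conc)
  )
  structure(
    list(
      rr = rr, ci = ci,
      interaction = classify_interaction(ci, additive_band),
      additive_band = additive_band,
      isobologram_point = pt, additivity_line = line, point_side = side,
      connection_curve = curve$pars, curve_converged = curve$converged,
      drug_ic50 = exp$drug_ic50, modulator_ic50 = exp$modulator_ic50,
      combo_ic50 = exp$combo_ic50, modulator_conc = exp$modulator_conc,
      schedule_id = exp$schedule_id
    ),
    class = "synergy_result"
  )
}

# exponential connection y = (top - bottom) exp(-k x) + bottom through the
# two intercepts and the combination point; purely a figure element
fit_connection_curve <- function(x, y) {
  d <- data.frame(x = x, y = y)
  top0 <- max(y); k0 <- 1 / max(x[x > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (top - bottom) * exp(-k * x) + bottom, data = d,
                      start = list(top = top0, bottom = min(y) - 0.1 * top0,
                                   k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    list(pars = c(top = NA_real_, bottom = NA_real_, k = NA_real_),
         converged = FALSE)
  } else {
    list(pars = coef(fit)[c("top", "bottom", "k")], converged = TRUE)
  }
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result>", if (!is.na(x$schedule_id)) x$schedule_id, "\n")
  cat(sprintf("  RR %.2f  CI %.2f  -> %s (point %s additivity line)\n",
              x$rr, x$ci, x$interaction, x$point_side))
  invisible(x)
}

#' Synergy results for a table of combination fits
#'
#' Joins a fitted-plate table (from [fit_plate()]) against itself to
#' form one [combination_experiment()] per (drug, modulator,
#' modulator concentration, schedule) and evaluates RR, CI and the
#' interaction call. The modulator-alone IC50 is taken at the *same
#' schedule* as the combination.
#'
#' @param fits A tibble from [fit_plate()] covering drug-alone,
#'   modulator-alone and combination conditions.
#' @param design A data frame with columns `drug`, `modulator`,
#'   `modulator_conc_uM`, `schedule` listing the combinations to score.
#' @param additive_band Half-width of the CI additivity band.
#' @return A tibble with one row per design row: IC50 inputs, `rr`,
#'   `ci`, `interaction`, and the `synergy_result` in a list-column.
#' @export
synergy_table <- function(fits, design, additive_band = 0.05) {
  lookup_ic50 <- function(compound, modulator, modulator_conc, schedule) {
    mod_match <- if (is.na(modulator)) {
      is.na(fits$modulator)
    } else {
      !is.na(fits$modulator) & fits$modulator == modulator &
        fits$modulator_conc_uM == modulator_conc
    }
    row <- fits[fits$compound == compound & fits$schedule == schedule &
                  mod_match, ]
    if (nrow(row) != 1) {
      abort(sprintf(
        "expected exactly one fit for (%s, modulator %s at %s uM, schedule %s); found %d.",
        compound, modulator %||% "none", format(modulator_conc), schedule,
        nrow(row)))
    }
    row$ic50
  }
  purrr::pmap_dfr(design, function(drug, modulator, modulator_conc_uM,
                                   schedule, ...) {
    exp <- combination_experiment(
      drug_fit_alone = lookup_ic50(drug, NA, NA, schedule),
      modulator_fit_alone = lookup_ic50(modulator, NA, NA, schedule),
      modulator_conc = modulator_conc_uM,
      combo_fit = lookup_ic50(drug, modulator, modulator_conc_uM, schedule),
      schedule_id = schedule
    )
    res <- isobologram(exp, additive_band)
    tibble::tibble(
      drug = drug, modulator = modulator,
      modulator_conc_uM = modulator_conc_uM, schedule = schedule,
      drug_ic50 = res$drug_ic50, modulator_ic50 = res$modulator_ic50,
      combo_ic50 = res$combo_ic50,
      rr = res$rr, ci = res$ci, interaction = res$interaction,
      result = list(res)
    )
  })
}
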