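#' Read a viability plate table
#'
#' Reads one well per row from delimited text (comma or tab, detected
#' from the header line). Expected columns:
#' `compound, conc_uM, modulator, modulator_conc_uM, schedule,
#' experiment, replicate, response, response_kind`. Vehicle-control
#' rows have `conc_uM = 0` and `modulator_conc_uM = 0`.
#'
#' @param path Path to a delimited text file.
#' @return A tibble of wells, validated by [validate_plate()].
#' @export
read_plate <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  plate <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      compound = readr::col_character(),
      conc_uM = readr::col_double(),
      modulator = readr::col_character(),
      modulator_conc_uM = readr::col_double(),
      schedule = readr::col_character(),
      experiment = readr::col_integer(),
      replicate = readr::col_integer(),
      response = readr::col_double(),
      response_kind = readr::col_character()
    )
  )
  validate_plate(plate, path = path)
}

#' Write a viability plate table
#'
#' @param plate A plate tibble.
#' @param path Output path; written as comma-delimited text.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  readr::write_csv(plate, path, progress = FALSE)
  invisible(path)
}

plate_columns <- c("compound", "conc_uM", "modulator", "modulator_conc_uM",
                   "schedule", "experiment", "replicate", "response",
                   "response_kind")

#' Validate a plate table
#'
#' Enforces the well-table schema: required columns, finite
#' non-negative concentrations and responses, replicate/experiment
#' indices >= 1, a single `response_kind` among `absorbance`,
#' `percent_viability`, `percent_inhibition`, and at least one
#' vehicle-control well (`conc_uM = 0`, `modulator_conc_uM = 0`) per
#' `(schedule, experiment)` group. Every malformed row is reported
#' with its row number and field.
#'
#' @param plate A data frame of wells.
#' @param path Optional file name used to prefix error messages.
#' @return The validated plate as a tibble.
#' @export
validate_plate <- function(plate, path = "<plate>") {
  missing_cols <- setdiff(plate_columns, names(plate))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  plate <- tibble::as_tibble(plate)
  problems <- character()
  bad <- function(rows, field, why) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("%s: row %d, field `%s`: %s",
                                       path, rows, field, why))
    }
  }
  bad(which(!is.finite(plate$conc_uM) | plate$conc_uM < 0),
      "conc_uM", "must be finite and >= 0")
  bad(which(!is.finite(plate$modulator_conc_uM) | plate$modulator_conc_uM < 0),
      "modulator_conc_uM", "must be finite and >= 0")
  bad(which(!is.finite(plate$response) | plate$response < 0),
      "response", "must be finite and >= 0")
  bad(which(is.na(plate$experiment) | plate$experiment < 1),
      "experiment", "must be an integer >= 1")
  bad(which(is.na(plate$replicate) | plate$replicate < 1),
      "replicate", "must be an integer >= 1")
  kinds <- c("absorbance", "percent_viability", "percent_inhibition")
  bad(which(!plate$response_kind %in% kinds), "response_kind",
      paste("must be one of", paste(kinds, collapse = "/")))
  if (length(problems) > 0) {
    abort(paste(head(problems, 10), collapse = "\n"))
  }
  no_vehicle <- plate |>
    dplyr::group_by(.data$schedule, .data$experiment) |>
    dplyr::summarise(
      has_vehicle = any(.data$conc_uM == 0 & .data$modulator_conc_uM == 0),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$has_vehicle)
  if (nrow(no_vehicle) > 0) {
    abort(sprintf(
      "%s: no vehicle-control well (conc_uM = 0, modulator_conc_uM = 0) in group(s): %s",
      path,
      paste(sprintf("(schedule %s, experiment %d)", no_vehicle$schedule,
                    no_vehicle$experiment), collapse = ", ")))
  }
  plate
}

#' Normalize plate responses to percent inhibition
#'
#' Within each `(schedule, experiment)` group, percent viability is the
#' well response expressed relative to the mean of that group's
#' vehicle-control wells (`100 * well / mean(vehicle)`); percent
#' inhibition is `100 - viability`. Vehicle wells therefore map to 0%
#' inhibition on average, and the ordering of wells by raw response is
#' exactly reversed in the inhibition scale within a group.
#'
#' @param plate A plate tibble with `response_kind` `"absorbance"` or
#'   `"percent_viability"`.
#' @return The plate with `response` replaced by percent inhibition and
#'   `response_kind = "percent_inhibition"`.
#' @export
normalize_viability <- function(plate) {
  plate <- validate_plate(plate)
  kind <- unique(plate$response_kind)
  if (length(kind) != 1 || kind == "percent_inhibition") {
    abort("plate must hold a single response_kind of absorbance or percent_viability.")
  }
  out <- plate |>
    dplyr::group_by(.data$schedule, .data$experiment) |>
    dplyr::group_modify(function(g, key) {
      veh <- g$response[g$conc_uM == 0 & g$modulator_conc_uM == 0]
      vm <- mean(veh)
      if (!is.finite(vm) || vm <= 0) {
        abort(sprintf(
          "non-positive vehicle mean in group (schedule %s, experiment %d).",
          key$schedule, key$experiment))
      }
      g$response <- 100 - 100 * g$response / vm
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(response_kind = "percent_inhibition") |>
    dplyr::relocate(dplyr::all_of(plate_columns))
  out
}

#' Fit Hill curves to every condition on a normalized plate
#'
#' Groups the plate by `(compound, modulator, modulator_conc_uM,
#' schedule)` and fits one Hill curve per group on the well-level
#' points (replicates are not averaged; the well-to-well variance is
#' what the bootstrap resamples).
#'
#' @param plate A normalized plate (`response_kind =
#'   "percent_inhibition"`); run [normalize_viability()] first if
#'   needed.
#' @param options A [fit_options()].
#' @param confidence Compute IC50 confidence limits per
#'   [ic50_confidence()] (bootstrap when `options$n_boot > 0`)?
#'   Default `FALSE`: the cheap asymptotic limits stored by
#'   [fit_hill()] are kept.
#' @return A tibble with one row per condition: the grouping columns,
#'   the `hill_fit` in a list-column `fit`, and unnested `ic50`,
#'   `ic50_lower`, `ic50_upper`, `emax`, `hill_slope`, `converged`.
#' @export
fit_plate <- function(plate, options = fit_options(), confidence = FALSE) {
  if (!all(plate$response_kind == "percent_inhibition")) {
    plate <- normalize_viability(plate)
  }
  plate |>
    dplyr::filter(.data$conc_uM > 0) |>
    dplyr::group_by(.data$compound, .data$modulator,
                    .data$modulator_conc_uM, .data$schedule) |>
    dplyr::group_modify(function(g, key) {
      d <- tibble::tibble(conc = g$conc_uM, inhibition = g$response)
      hf <- fit_hill(d, options)
      if (confidence) hf <- ic50_confidence(d, hf, options)
      tibble::tibble(
        fit = list(hf), ic50 = hf$ic50,
        ic50_lower = hf$ic50_cl[["lower"]],
        ic50_upper = hf$ic50_cl[["upper"]],
        emax = hf$emax, hill_slope = hf$hill_slope,
        converged = hf$converged
      )
    }) |>
    dplyr::ungroup()
}
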