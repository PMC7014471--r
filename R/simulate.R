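#' Canonical exposure-schedule library
#'
#' The six schedules of the default study: single long-term exposures
#' of 24, 48 and 72 h, and metronomic protocols of one, two or three
#' 2 h exposures (2 h functional recovery between repeats) followed by
#' a 72 h recovery before the viability read-out.
#'
#' @return A tibble with columns `schedule` (id), `blocks` (list-column
#'   of tibbles with `treatment_h`, `recovery_h`) and
#'   `total_exposure_h`.
#' @export
schedule_library <- function() {
  blk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(treatment_h = m[, 1], recovery_h = m[, 2])
  }
  tibble::tibble(
    schedule = c("24h", "48h", "72h", "2h", "2hx2", "2hx3"),
    blocks = list(
      blk(24, 0), blk(48, 0), blk(72, 0),
      blk(2, 72),
      blk(2, 2, 2, 72),
      blk(2, 2, 2, 2, 2, 72)
    )
  ) |>
    dplyr::mutate(total_exposure_h = purrr::map_dbl(.data$blocks,
                                                    ~ sum(.x$treatment_h)))
}

#' Default ground truth for the synthetic study
#'
#' Drug-level truth (base IC50 at the 24 h reference schedule, maximal
#' inhibition, Hill slope, and a multiplicative IC50 factor per
#' schedule) and interaction truth (a potency-shift `rho` per
#' drug-modulator-concentration-schedule cell). Factors are the ratios
#' of the published per-schedule IC50s to the 24 h value, so e.g.
#' doxorubicin carries factors 0.25 (48 h), 0.111 (72 h), 0.944 (2 h),
#' 0.806 (2 h x2) and 0.403 (2 h x3). In the presence of modulator B at
#' concentration `c_b`, the drug's effective IC50 is
#' `base * factor * rho`, which makes the noiseless (analytic)
#' combination index `rho + c_b / ic50_B` — see [analytic_ci()]. `rho`
#' is chosen to reproduce the published CI for the schedules where one
#' was reported, and the published combination/alone IC50 ratio for
#' 48 h and 72 h.
#'
#' @return A list with elements `drugs` (tibble: `compound`,
#'   `base_ic50`, `emax`, `hill_slope`, `reference_schedule`),
#'   `schedule_potency` (tibble: `compound`, `schedule`, `factor`) and
#'   `interactions` (tibble: `drug`, `modulator`, `modulator_conc_uM`,
#'   `schedule`, `rho`, `analytic_ci`).
#' @export
make_default_truth <- function() {
  ref <- reference_ic50()
  base <- ref |>
    dplyr::filter(.data$schedule == "24h") |>
    dplyr::select("compound", base_ic50 = "ic50")
  drugs <- base |>
    dplyr::mutate(
      emax = dplyr::if_else(.data$compound == "doxorubicin", 88, 90),
      hill_slope = dplyr::if_else(.data$compound == "doxorubicin", 1.2, 1.6),
      reference_schedule = "24h"
    )
  schedule_potency <- ref |>
    dplyr::left_join(base, by = "compound") |>
    dplyr::mutate(factor = .data$ic50 / .data$base_ic50) |>
    dplyr::select("compound", "schedule", "factor")

  mod_ic50 <- ref |> dplyr::select("compound", "schedule", mod_ic50 = "ic50")
  combo <- reference_combination_ic50() |>
    dplyr::left_join(reference_ci(),
                     by = c("schedule", "modulator", "modulator_conc_uM")) |>
    dplyr::left_join(mod_ic50,
                     by = c("modulator" = "compound", "schedule")) |>
    dplyr::left_join(
      ref |> dplyr::filter(.data$compound == "doxorubicin") |>
        dplyr::select("schedule", drug_ic50 = "ic50"),
      by = "schedule"
    )
  interactions <- combo |>
    dplyr::mutate(
      drug = "doxorubicin",
      rho = dplyr::if_else(
        is.na(.data$ci_printed),
        .data$ic50 / .data$drug_ic50,
        .data$ci_printed - .data$modulator_conc_uM / .data$mod_ic50
      ),
      analytic_ci = .data$rho + .data$modulator_conc_uM / .data$mod_ic50
    ) |>
    dplyr::select("drug", "modulator", "modulator_conc_uM", "schedule",
                  "rho", "analytic_ci")
  list(drugs = drugs, schedule_potency = schedule_potency,
       interactions = interactions)
}

#' Noiseless combination index implied by the generator truth
#'
#' For a condition with potency shift `rho` and modulator held at
#' `modulator_conc`, the combination curve's IC50 is
#' `rho * ic50_drug`, so the CI equation collapses to
#' `rho + modulator_conc / modulator_ic50` — the value a perfect
#' pipeline recovers from noiseless plates.
#'
#' @param rho Potency-shift factor (> 0).
#' @param modulator_conc Fixed modulator concentration, µM.
#' @param modulator_ic50 Modulator-alone IC50 at the same schedule, µM.
#' @return Dimensionless CI (vectorized).
#' @export
analytic_ci <- function(rho, modulator_conc, modulator_ic50) {
  if (any(rho <= 0) || any(modulator_ic50 <= 0) || any(modulator_conc < 0)) {
    abort("`rho` and `modulator_ic50` must be > 0; `modulator_conc` >= 0.")
  }
  rho + modulator_conc / modulator_ic50
}

#' Plate noise model
#'
#' Additive Gaussian noise on percent viability (default SD 6%),
#' an experiment-level absorbance scale drawn with coefficient of
#' variation `vehicle_cv`, and the replication structure: 2 independent
#' experiments with triplicate wells (n = 6 per condition) by default.
#'
#' @param sd_viability Additive noise SD on % viability (>= 0).
#' @param vehicle_cv Coefficient of variation of the per-experiment
#'   vehicle absorbance level.
#' @param n_experiments,n_replicates Replication structure.
#' @param seed Integer seed; identical seeds yield identical plates.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd_viability = 6, vehicle_cv = 0.05,
                        n_experiments = 2L, n_replicates = 3L, seed = 1L) {
  stopifnot(sd_viability >= 0, vehicle_cv >= 0,
            n_experiments >= 1, n_replicates >= 1)
  structure(
    list(sd_viability = sd_viability, vehicle_cv = vehicle_cv,
         n_experiments = as.integer(n_experiments),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "noise_model"
  )
}

# effective IC50 for a condition row under the truth
effective_ic50 <- function(truth, compound, schedule, modulator = NA,
                           modulator_conc = NA) {
  drug <- dplyr::filter(truth$drugs, .data$compound == .env$compound)
  if (nrow(drug) != 1) abort(sprintf("unknown compound `%s` in truth.", compound))
  fac <- truth$schedule_potency |>
    dplyr::filter(.data$compound == .env$compound,
                  .data$schedule == .env$schedule)
  if (nrow(fac) != 1) {
    abort(sprintf("no schedule factor for (%s, %s).", compound, schedule))
  }
  eff <- drug$base_ic50 * fac$factor
  if (!is.na(modulator) && !is.na(modulator_conc) && modulator_conc > 0) {
    inter <- truth$interactions |>
      dplyr::filter(.data$drug == .env$compound,
                    .data$modulator == .env$modulator,
                    .data$modulator_conc_uM == .env$modulator_conc,
                    .data$schedule == .env$schedule)
    if (nrow(inter) != 1) {
      abort(sprintf("no interaction truth for (%s + %s %g uM, %s).",
                    compound, modulator, modulator_conc, schedule))
    }
    eff <- eff * inter$rho
  }
  list(ic50 = eff, emax = drug$emax, hill_slope = drug$hill_slope)
}

#' Simulate one MTT viability plate
#'
#' Generates well-level absorbances for a set of conditions under the
#' generator truth: true percent viability is
#' `100 - hill_response(conc)` at the condition's effective IC50
#' (schedule factor applied, interaction shift applied when a modulator
#' is present), additive Gaussian noise on the viability scale is
#' added and clipped at 0, and wells are expressed as absorbances on a
#' per-experiment vehicle scale. Vehicle-control wells (conc 0, no
#' modulator) are included per `(schedule, experiment)` group.
#' Generation is deterministic given `noise$seed`.
#'
#' @param design A data frame with one row per (condition,
#'   concentration): columns `compound`, `conc_uM`, `modulator` (NA for
#'   none), `modulator_conc_uM`, `schedule`. Concentrations should
#'   bracket the condition's effective IC50 (a warning is issued
#'   otherwise).
#' @param truth A truth list as returned by [make_default_truth()].
#' @param noise A [noise_model()].
#' @return A validated plate tibble (`response_kind = "absorbance"`).
#' @export
simulate_plate <- function(design, truth, noise = noise_model()) {
  if (nrow(design) == 0) abort("empty design.")
  design <- tibble::as_tibble(design)
  if (!"modulator" %in% names(design)) design$modulator <- NA_character_
  if (!"modulator_conc_uM" %in% names(design)) design$modulator_conc_uM <- 0
  design$modulator_conc_uM[is.na(design$modulator_conc_uM)] <- 0

  cond <- design |>
    dplyr::distinct(.data$compound, .data$modulator, .data$modulator_conc_uM,
                    .data$schedule)
  eff <- purrr::pmap(cond, function(compound, modulator, modulator_conc_uM,
                                    schedule) {
    e <- effective_ic50(truth, compound, schedule, modulator,
                        modulator_conc_uM)
    same_mod <- if (is.na(modulator)) is.na(design$modulator) else
      !is.na(design$modulator) & design$modulator == modulator &
        design$modulator_conc_uM == modulator_conc_uM
    concs <- design$conc_uM[design$compound == compound &
                              design$schedule == schedule & same_mod]
    if (min(concs) > e$ic50 || max(concs) < e$ic50) {
      warn(sprintf(
        "design for (%s%s, %s) does not bracket the effective IC50 %.3g uM.",
        compound,
        if (!is.na(modulator)) paste0(" + ", modulator, " ", modulator_conc_uM) else "",
        schedule, e$ic50))
    }
    tibble::tibble(compound = compound, modulator = modulator,
                   modulator_conc_uM = modulator_conc_uM, schedule = schedule,
                   eff_ic50 = e$ic50, emax = e$emax, hill_slope = e$hill_slope)
  }) |> dplyr::bind_rows()

  rows <- design |>
    dplyr::left_join(eff, by = c("compound", "modulator",
                                 "modulator_conc_uM", "schedule"))
  withr::with_seed(noise$seed, {
    wells <- tidyr::expand_grid(
      rows,
      experiment = seq_len(noise$n_experiments),
      replicate = seq_len(noise$n_replicates)
    )
    # rowwise Hill evaluation (parameters vary by condition); conc > 0
    # throughout the design, so the closed form applies directly
    wells$true_inhibition <- wells$emax /
      (1 + 10^(wells$hill_slope * (log10(wells$eff_ic50) -
                                     log10(wells$conc_uM))))
    vehicles <- wells |>
      dplyr::distinct(.data$schedule, .data$experiment) |>
      tidyr::expand_grid(replicate = seq_len(noise$n_replicates)) |>
      dplyr::mutate(
        compound = "vehicle", conc_uM = 0, modulator = NA_character_,
        modulator_conc_uM = 0, true_inhibition = 0
      )
    all_wells <- dplyr::bind_rows(
      wells[c("compound", "conc_uM", "modulator", "modulator_conc_uM",
              "schedule", "experiment", "replicate", "true_inhibition")],
      vehicles[c("compound", "conc_uM", "modulator", "modulator_conc_uM",
                 "schedule", "experiment", "replicate", "true_inhibition")]
    )
    scale_tbl <- all_wells |>
      dplyr::distinct(.data$schedule, .data$experiment) |>
      dplyr::mutate(base_abs = 1 * (1 + rnorm(dplyr::n(), 0,
                                              noise$vehicle_cv)))
    all_wells |>
      dplyr::left_join(scale_tbl, by = c("schedule", "experiment")) |>
      dplyr::mutate(
        viability = pmax(0, 100 - .data$true_inhibition +
                           rnorm(dplyr::n(), 0, noise$sd_viability)),
        response = .data$base_abs * .data$viability / 100,
        response_kind = "absorbance"
      ) |>
      dplyr::select(dplyr::all_of(plate_columns)) |>
      dplyr::arrange(.data$schedule, .data$compound, .data$modulator,
                     .data$modulator_conc_uM, .data$conc_uM,
                     .data$experiment, .data$replicate) |>
      validate_plate(path = "<simulated>")
  })
}

#' Default concentration grids of the synthetic study
#'
#' @return A list with `drug_alone` (doxorubicin gradient, µM),
#'   `modulator_alone` (sesquiterpene gradient, µM) and `combo_drug`
#'   (doxorubicin gradient used on combination rays, extended downward
#'   so strongly potentiated effective IC50s stay bracketed).
#' @export
default_grids <- function() {
  list(
    drug_alone = c(1, 2, 5, 10, 20, 50, 100),
    modulator_alone = c(2.5, 10, 25, 50, 125, 250, 375, 500),
    combo_drug = c(0.25, 0.5, 1, 2, 5, 10, 20, 50, 100)
  )
}

#' Study configuration for the synthetic generator
#'
#' @param truth Truth list; defaults to [make_default_truth()].
#' @param noise A [noise_model()]; its `seed` is used as the master
#'   seed.
#' @param grids Concentration grids, see [default_grids()].
#' @param schedules Character vector of schedule ids to simulate.
#' @return A list of class `study_config`.
#' @export
study_config <- function(truth = make_default_truth(),
                         noise = noise_model(),
                         grids = default_grids(),
                         schedules = schedule_library()$schedule) {
  structure(list(truth = truth, noise = noise, grids = grids,
                 schedules = schedules),
            class = "study_config")
}

# master seed -> per-plate child seed; documented counter scheme so any
# single plate can be regenerated in isolation
child_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m + 7919 * as.numeric(index)) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Simulate the full default study
#'
#' Emits one plate per schedule for each drug alone (doxorubicin and
#' both sesquiterpenes — all three solo curves are needed because the
#' combination index uses the same-schedule modulator IC50) and one
#' per fixed-modulator combination ray (each sesquiterpene at 50 and
#' 100 µM), plus a truth manifest holding the generator parameters,
#' per-plate child seeds and the analytic CI of every combination
#' condition. Child seeds derive from the master seed by a linear
#' counter scheme (`(master + 7919 * plate_index) mod (2^31 - 1)`), so
#' single plates are reproducible in isolation with [simulate_plate()].
#'
#' @param config A [study_config()].
#' @return A list with `plates` (named list of plate tibbles) and
#'   `manifest` (a JSON-serializable list: master seed, noise
#'   parameters, truth tables, per-plate seeds, and per-condition
#'   analytic CIs).
#' @export
simulate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) abort("`config` must be a study_config.")
  truth <- config$truth; noise <- config$noise; grids <- config$grids
  conds <- list()
  for (sch in config$schedules) {
    for (cmp in truth$drugs$compound) {
      grid <- if (cmp == "doxorubicin") grids$drug_alone else
        grids$modulator_alone
      conds[[paste(cmp, sch, sep = "_")]] <- tibble::tibble(
        compound = cmp, conc_uM = grid, modulator = NA_character_,
        modulator_conc_uM = 0, schedule = sch
      )
    }
    inter <- dplyr::filter(truth$interactions, .data$schedule == sch)
    for (i in seq_len(nrow(inter))) {
      nm <- paste(inter$drug[i], inter$modulator[i],
                  inter$modulator_conc_uM[i], sch, sep = "_")
      conds[[nm]] <- tibble::tibble(
        compound = inter$drug[i], conc_uM = grids$combo_drug,
        modulator = inter$modulator[i],
        modulator_conc_uM = inter$modulator_conc_uM[i], schedule = sch
      )
    }
  }
  plate_names <- names(conds)
  seeds <- child_seed(noise$seed, seq_along(conds))
  plates <- purrr::map2(conds, seeds, function(d, s) {
    n <- noise; n$seed <- s
    simulate_plate(d, truth, n)
  })
  names(plates) <- plate_names
  mod_ic50 <- reference_ic50() |>
    dplyr::select("compound", "schedule", mod_ic50 = "ic50")
  conditions <- truth$interactions |>
    dplyr::filter(.data$schedule %in% config$schedules) |>
    dplyr::left_join(mod_ic50, by = c("modulator" = "compound", "schedule"))
  manifest <- list(
    master_seed = noise$seed,
    noise = unclass(noise),
    drugs = truth$drugs,
    schedule_potency = truth$schedule_potency,
    conditions = conditions,
    plates = tibble::tibble(plate = plate_names, seed = seeds)
  )
  list(plates = plates, manifest = manifest)
}

#' Write a simulated study to disk
#'
#' One comma-delimited plate file per plate plus
#' `truth_manifest.json`.
#'
#' @param study The result of [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$plates)) {
    write_plate(study$plates[[nm]], file.path(outdir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(study$manifest,
                       file.path(outdir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
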