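#' Analyze a set of viability plates end to end
#'
#' Normalizes each plate to percent inhibition, fits one Hill curve per
#' condition, and scores every combination in `design` (reversal ratio,
#' combination index, interaction call, isobologram geometry) under the
#' same-schedule convention for the modulator-alone IC50.
#'
#' @param plates A named list of plate tibbles (or a single plate).
#'   Each plate is normalized against its own vehicle wells.
#' @param design Data frame with `drug`, `modulator`,
#'   `modulator_conc_uM`, `schedule`; defaults to every combination
#'   condition present in the fitted table.
#' @param options A [fit_options()].
#' @param additive_band CI additivity half-band.
#' @param confidence Compute bootstrap/asymptotic IC50 limits per fit
#'   (slower); see [fit_plate()].
#' @return A list with `fits` (tibble from [fit_plate()]) and `synergy`
#'   (tibble from [synergy_table()]).
#' @export
analyze_plates <- function(plates, design = NULL, options = fit_options(),
                           additive_band = 0.05, confidence = FALSE) {
  if (is.data.frame(plates)) plates <- list(plates)
  normalized <- purrr::map(plates, normalize_viability) |>
    dplyr::bind_rows()
  fits <- fit_plate(normalized, options, confidence = confidence)
  if (is.null(design)) {
    design <- fits |>
      dplyr::filter(!is.na(.data$modulator)) |>
      dplyr::distinct(drug = .data$compound, modulator = .data$modulator,
                      modulator_conc_uM = .data$modulator_conc_uM,
                      schedule = .data$schedule)
  }
  synergy <- if (nrow(design) > 0) {
    synergy_table(fits, design, additive_band)
  } else {
    tibble::tibble()
  }
  list(fits = fits, synergy = synergy)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (or load) -> normalize -> fit -> synergy and
#' writes JSON results plus a run manifest. The configuration is a
#' list, or a path to a JSON/YAML file, with fields:
#' \describe{
#'   \item{seed}{Master seed; every source of randomness (simulation,
#'     bootstrap) derives from it. Recorded in all outputs.}
#'   \item{simulate}{Logical; `TRUE` generates the default synthetic
#'     study (exactly one of `simulate` / `plate_paths` must be set).}
#'   \item{plate_paths}{Character vector of plate files to load
#'     instead of simulating.}
#'   \item{sd_viability, n_experiments, n_replicates}{Noise-model
#'     overrides for simulation.}
#'   \item{additive_band}{CI additivity half-band (default 0.05).}
#'   \item{n_boot}{Bootstrap resamples for IC50 limits (0 = Wald;
#'     default 0 inside the pipeline for speed).}
#'   \item{outdir}{Output directory; omit to skip writing.}
#' }
#' Reruns with identical inputs and seed produce byte-identical JSON
#' outputs (checksums are in the manifest).
#'
#' @param config List or path, as above.
#' @return A list `fits`, `synergy`, `manifest` (invisible elements
#'   also written under `outdir` when given).
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  seed <- as.integer(config$seed %||% 1L)
  simulate <- isTRUE(config$simulate)
  has_paths <- !is.null(config$plate_paths)
  if (simulate == has_paths) {
    abort("exactly one of `simulate = TRUE` or `plate_paths` must be given.")
  }
  manifest_truth <- NULL
  if (simulate) {
    nm <- noise_model(
      sd_viability = config$sd_viability %||% 6,
      vehicle_cv = config$vehicle_cv %||% 0.05,
      n_experiments = config$n_experiments %||% 2L,
      n_replicates = config$n_replicates %||% 3L,
      seed = seed
    )
    study <- simulate_study(study_config(noise = nm))
    plates <- study$plates
    manifest_truth <- study$manifest
    inputs <- "simulated default study"
  } else {
    plates <- purrr::map(config$plate_paths, read_plate)
    names(plates) <- basename(config$plate_paths)
    inputs <- config$plate_paths
  }
  options <- fit_options(n_boot = config$n_boot %||% 0L, seed = seed)
  res <- analyze_plates(plates, design = config$design,
                        options = options,
                        additive_band = config$additive_band %||% 0.05,
                        confidence = (config$n_boot %||% 0L) > 0)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metrosyn")),
    seed = seed,
    inputs = inputs,
    n_plates = length(plates),
    n_fits = nrow(res$fits),
    n_synergy = nrow(res$synergy)
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    fits_out <- res$fits |> dplyr::select(-"fit")
    syn_out <- res$synergy
    if (nrow(syn_out) > 0) syn_out <- dplyr::select(syn_out, -"result")
    paths <- c(
      fits = file.path(config$outdir, "fits.json"),
      synergy = file.path(config$outdir, "synergy.json")
    )
    jsonlite::write_json(fits_out, paths[["fits"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(syn_out, paths[["synergy"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (!is.null(manifest_truth)) {
      jsonlite::write_json(manifest_truth,
                           file.path(config$outdir, "truth_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      paths <- c(paths,
                 truth = file.path(config$outdir, "truth_manifest.json"))
    }
    manifest$outputs <- as.list(setNames(unname(tools::md5sum(paths)),
                                         basename(paths)))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(fits = res$fits, synergy = res$synergy,
                 manifest = manifest, truth = manifest_truth))
}
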