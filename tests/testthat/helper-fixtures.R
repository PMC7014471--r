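# deterministic concentration-inhibition data from a known Hill curve
make_hill_data <- function(emax = 88, ic50 = 14.4, slope = 1.2,
                           conc = c(1, 2, 5, 10, 20, 50, 100),
                           reps = 3, sd = 0, seed = 1) {
  d <- tidyr::expand_grid(conc = conc, rep = seq_len(reps))
  d$inhibition <- hill_response(d$conc, emax, log10(ic50), slope)
  if (sd > 0) {
    d$inhibition <- withr::with_seed(seed,
                                     d$inhibition + rnorm(nrow(d), 0, sd))
  }
  d[c("conc", "inhibition")]
}

# minimal raw-absorbance plate: one compound, one schedule, with vehicles
make_mini_plate <- function(inhibition_by_conc, vehicle_abs = 1.0,
                            schedule = "24h", experiment = 1L) {
  conc <- as.numeric(names(inhibition_by_conc))
  tibble::tibble(
    compound = c(rep("drugA", length(conc)), "vehicle"),
    conc_uM = c(conc, 0),
    modulator = NA_character_,
    modulator_conc_uM = 0,
    schedule = schedule,
    experiment = as.integer(experiment),
    replicate = 1L,
    response = c(vehicle_abs * (100 - unname(inhibition_by_conc)) / 100,
                 vehicle_abs),
    response_kind = "absorbance"
  )
}

# alone + combination plates for one combination condition; zero noise by
# default so estimates are exact
simulate_condition_set <- function(truth, schedule, modulator, mod_conc,
                                   sd = 0, seed = 1) {
  grids <- default_grids()
  noise <- noise_model(sd_viability = sd, vehicle_cv = if (sd > 0) 0.05 else 0,
                       seed = seed)
  des <- list(
    drug = tibble::tibble(compound = "doxorubicin",
                          conc_uM = grids$drug_alone,
                          modulator = NA_character_, modulator_conc_uM = 0,
                          schedule = schedule),
    mod = tibble::tibble(compound = modulator,
                         conc_uM = grids$modulator_alone,
                         modulator = NA_character_, modulator_conc_uM = 0,
                         schedule = schedule),
    combo = tibble::tibble(compound = "doxorubicin",
                           conc_uM = grids$combo_drug,
                           modulator = modulator,
                           modulator_conc_uM = mod_conc, schedule = schedule)
  )
  purrr::imap(des, function(d, nm) {
    n <- noise; n$seed <- child_seed_for_tests(seed, match(nm, names(des)))
    simulate_plate(d, truth, n)
  })
}

child_seed_for_tests <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * index) %% 2147483647)
}

energy_fixture <- function() {
  system.file("extdata", "pgp_mmpbsa_energies.tsv", package = "metrosyn")
}
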