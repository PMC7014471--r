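#' Published solo IC50 reference values (HepG2, MTT)
#'
#' Point estimates and confidence limits of the IC50 (µM) of
#' doxorubicin, beta-caryophyllene and beta-caryophyllene oxide in
#' HepG2 cells, from a published MTT study run under single long-term
#' exposures (24/48/72 h) and metronomic schedules (2 h exposures,
#' single/double/triple, each followed by a 72 h recovery). These
#' values parameterize the default synthetic-study truth
#' ([make_default_truth()]) and serve as worked-example inputs for the
#' combination-index machinery.
#'
#' @return A tibble with columns `compound`, `schedule`, `ic50`,
#'   `cl_lower`, `cl_upper` (all concentrations in µM).
#' @export
reference_ic50 <- function() {
  tibble::tribble(
    ~compound,                  ~schedule, ~ic50, ~cl_lower, ~cl_upper,
    "doxorubicin",              "24h",      14.4,      12.8,      16.2,
    "doxorubicin",              "48h",       3.6,       2.6,       5.2,
    "doxorubicin",              "72h",       1.6,       1.4,       1.8,
    "doxorubicin",              "2h",       13.6,       2.6,      20.2,
    "doxorubicin",              "2hx2",     11.6,       6.4,      20.4,
    "doxorubicin",              "2hx3",      5.8,       2.8,      11.6,
    "beta_caryophyllene",       "24h",     197.0,     127.0,     314.5,
    "beta_caryophyllene",       "48h",     121.0,      94.0,     159.5,
    "beta_caryophyllene",       "72h",     113.0,      88.5,     144.0,
    "beta_caryophyllene",       "2h",      379.5,     171.5,     460.5,
    "beta_caryophyllene",       "2hx2",    265.5,     110.5,     327.0,
    "beta_caryophyllene",       "2hx3",    251.0,      71.5,     372.0,
    "beta_caryophyllene_oxide", "24h",     195.0,     172.5,     219.5,
    "beta_caryophyllene_oxide", "48h",     162.0,     146.0,     180.0,
    "beta_caryophyllene_oxide", "72h",     152.5,     136.5,     170.0,
    "beta_caryophyllene_oxide", "2h",      354.5,     190.5,     441.0,
    "beta_caryophyllene_oxide", "2hx2",    281.0,     157.5,     360.5,
    "beta_caryophyllene_oxide", "2hx3",    256.5,     123.5,     334.0
  )
}

#' Published combination IC50 reference values (HepG2, MTT)
#'
#' Doxorubicin IC50 (µM) when titrated against a fixed chemosensitizing
#' concentration (50 or 100 µM) of beta-caryophyllene or
#' beta-caryophyllene oxide, per exposure schedule, with the published
#' reversal ratios.
#'
#' @return A tibble with columns `schedule`, `modulator`,
#'   `modulator_conc_uM`, `ic50`, `cl_lower`, `cl_upper`, `rr_printed`.
#' @export
reference_combination_ic50 <- function() {
  tibble::tribble(
    ~schedule, ~modulator,                 ~modulator_conc_uM, ~ic50, ~cl_lower, ~cl_upper, ~rr_printed,
    "24h",  "beta_caryophyllene",        50,  8.6, 7.6, 13.8,  1.7,
    "24h",  "beta_caryophyllene",       100,  1.0, 0.4,  1.8, 14.4,
    "24h",  "beta_caryophyllene_oxide",  50,  5.0, 4.2,  5.8,  2.9,
    "24h",  "beta_caryophyllene_oxide", 100,  3.4, 2.2,  4.6,  4.2,
    "48h",  "beta_caryophyllene",        50,  3.2, 2.0,  5.2,  1.4,
    "48h",  "beta_caryophyllene",       100,  2.8, 1.2,  5.2,  1.7,
    "48h",  "beta_caryophyllene_oxide",  50,  3.2, 1.6,  5.2,  1.6,
    "48h",  "beta_caryophyllene_oxide", 100,  2.8, 1.2,  4.8,  1.8,
    "72h",  "beta_caryophyllene",        50,  1.0, 0.8,  1.4,  1.6,
    "72h",  "beta_caryophyllene",       100,  1.2, 0.6,  3.4,  1.3,
    "72h",  "beta_caryophyllene_oxide",  50,  1.0, 0.8,  1.6,  1.6,
    "72h",  "beta_caryophyllene_oxide", 100,  1.2, 0.6,  2.6,  1.3,
    "2h",   "beta_caryophyllene",        50,  8.2, 3.2, 21.4,  1.7,
    "2h",   "beta_caryophyllene",       100,  3.6, 1.8,  7.2,  3.8,
    "2h",   "beta_caryophyllene_oxide",  50,  6.6, 2.4, 18.0,  2.1,
    "2h",   "beta_caryophyllene_oxide", 100,  8.6, 5.0, 14.0,  1.6,
    "2hx2", "beta_caryophyllene",        50,  3.2, 1.4,  7.0,  2.6,
    "2hx2", "beta_caryophyllene",       100,  4.6, 2.2,  9.6,  1.8,
    "2hx2", "beta_caryophyllene_oxide",  50,  2.2, 0.2,  8.4,  3.7,
    "2hx2", "beta_caryophyllene_oxide", 100,  5.6, 2.6, 12.2,  1.5,
    "2hx3", "beta_caryophyllene",        50,  3.2, 1.8,  5.4,  1.8,
    "2hx3", "beta_caryophyllene",       100,  3.4, 2.0,  6.6,  1.7,
    "2hx3", "beta_caryophyllene_oxide",  50,  4.6, 3.0,  6.2,  1.3,
    "2hx3", "beta_caryophyllene_oxide", 100,  5.4, 3.6,  9.0,  1.1
  )
}

#' Published combination index values (HepG2, MTT)
#'
#' Combination index values reported for doxorubicin plus a fixed
#' chemosensitizing concentration of each sesquiterpene, per schedule.
#' Printed CIs were computed by the original analysts from unrounded
#' curve fits, so a few differ by 0.01 from the value recomputed from
#' the rounded reference IC50 tables.
#'
#' @return A tibble with columns `schedule`, `modulator`,
#'   `modulator_conc_uM`, `ci_printed`.
#' @export
reference_ci <- function() {
  tibble::tribble(
    ~schedule, ~modulator,                 ~modulator_conc_uM, ~ci_printed,
    "24h",  "beta_caryophyllene",        50, 0.85,
    "24h",  "beta_caryophyllene",       100, 0.58,
    "24h",  "beta_caryophyllene_oxide",  50, 0.61,
    "24h",  "beta_caryophyllene_oxide", 100, 0.75,
    "2h",   "beta_caryophyllene",        50, 0.73,
    "2h",   "beta_caryophyllene",       100, 0.52,
    "2h",   "beta_caryophyllene_oxide",  50, 0.62,
    "2h",   "beta_caryophyllene_oxide", 100, 0.91,
    "2hx2", "beta_caryophyllene",        50, 0.58,
    "2hx2", "beta_caryophyllene",       100, 0.94,
    "2hx2", "beta_caryophyllene_oxide",  50, 0.44,
    "2hx2", "beta_caryophyllene_oxide", 100, 1.02,
    "2hx3", "beta_caryophyllene",        50, 0.75,
    "2hx3", "beta_caryophyllene",       100, 0.99,
    "2hx3", "beta_caryophyllene_oxide",  50, 0.99,
    "2hx3", "beta_caryophyllene_oxide", 100, 1.30
  )
}

#' Molar masses of the default-study compounds
#'
#' @return Named numeric vector, g/mol (doxorubicin as the
#'   hydrochloride salt).
#' @export
reference_molar_mass <- function() {
  c(doxorubicin = 579.98, beta_caryophyllene = 204.35,
    beta_caryophyllene_oxide = 220.35)
}
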