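Package: metrosyn
Title: Dose-Response, Combination-Index and Isobologram Analysis for
    Metronomic Chemosensitization Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying drug-combination cytotoxicity in
    plate-based viability assays run under standard long-term and
    metronomic (short repeated) exposure schedules. Implements Hill
    concentration-response fitting with bootstrap or asymptotic IC50
    confidence limits, reversal-ratio and combination-index statistics
    with isobologram geometry for fixed-modulator combination designs,
    a synthetic MTT-plate generator with exported ground truth for
    pipeline validation, and a validator/reporter for MM-PBSA
    binding-energy decomposition tables and per-residue contribution
    profiles. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
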