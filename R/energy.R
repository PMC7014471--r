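#' Read an MM-PBSA energy decomposition table
#'
#' Parses a delimited text table (comma or tab) of per-ligand binding
#' free-energy components, one ligand per row, columns `ligand`, `vdw`,
#' `electrostatic`, `polar_solvation`, `sasa`, `mean_binding` (all in
#' kJ/mol). Unicode minus signs and en-dashes are normalized to ASCII
#' before parsing, since MM-PBSA tables copied from reports frequently
#' carry typographic minus characters.
#'
#' @param path Path to a delimited text file.
#' @return A validated tibble (class `energy_table`).
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort(sprintf("%s: schema error: expected a header and >= 1 data row.",
                  path))
  }
  lines <- gsub("−|–", "-", lines)
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  tbl <- readr::read_delim(I(paste(lines, collapse = "\n")), delim = delim,
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  energy_cols <- c("vdw", "electrostatic", "polar_solvation", "sasa",
                   "mean_binding")
  missing_cols <- setdiff(c("ligand", energy_cols), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: schema error: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in energy_cols) {
    vals <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0) {
      abort(sprintf("%s: row %d, column `%s`: non-numeric value \"%s\".",
                    path, bad[1], col, tbl[[col]][bad[1]]))
    }
    tbl[[col]] <- vals
  }
  if (anyDuplicated(tbl$ligand)) {
    abort(sprintf("%s: duplicated ligand id(s): %s", path,
                  paste(unique(tbl$ligand[duplicated(tbl$ligand)]),
                        collapse = ", ")))
  }
  structure(tibble::as_tibble(tbl), class = c("energy_table",
                                              class(tibble::tibble())))
}

#' Check the component-sum identity of an energy table
#'
#' The mean binding energy of each ligand must equal the sum of its
#' van der Waals, electrostatic, polar-solvation and SASA components.
#' With components rounded to 2 decimals the residual of a consistent
#' row is at most a couple of hundredths, hence the default tolerance
#' of 0.02 kJ/mol. Failures are rows of the report, not errors.
#'
#' @param table An [read_energy_table()] tibble (or any data frame with
#'   the five energy columns).
#' @param tol Tolerance in kJ/mol.
#' @return A tibble per ligand: `components_sum`, `mean_binding`,
#'   `residual` (absolute) and `pass`.
#' @export
validate_sums <- function(table, tol = 0.02) {
  stopifnot(tol >= 0)
  table |>
    dplyr::mutate(
      components_sum = .data$vdw + .data$electrostatic +
        .data$polar_solvation + .data$sasa,
      residual = abs(.data$components_sum - .data$mean_binding),
      pass = .data$residual <= tol
    ) |>
    dplyr::select("ligand", "components_sum", "mean_binding", "residual",
                  "pass") |>
    tibble::as_tibble()
}

#' Rank ligands by mean binding energy
#'
#' Most negative (strongest predicted binder) first; exact ties are
#' broken alphabetically by ligand id and flagged.
#'
#' @param table An energy table.
#' @return A tibble `ligand`, `mean_binding`, `rank`, `tied`.
#' @export
rank_by_binding <- function(table) {
  out <- table |>
    dplyr::arrange(.data$mean_binding, .data$ligand) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      tied = duplicated(.data$mean_binding) |
        duplicated(.data$mean_binding, fromLast = TRUE)
    ) |>
    dplyr::select("ligand", "mean_binding", "rank", "tied")
  tibble::as_tibble(out)
}

#' Read a per-residue contribution profile
#'
#' Two-column delimited text (`residue`, `energy` in kJ/mol); residue
#' labels such as "Leu225" must be unique.
#'
#' @param path Path to the file.
#' @param ligand_id Ligand the profile belongs to.
#' @return A tibble `ligand`, `residue`, `energy`.
#' @export
read_residue_profile <- function(path, ligand_id) {
  lines <- gsub("−|–", "-", readLines(path, warn = FALSE))
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  tbl <- readr::read_delim(I(paste(lines, collapse = "\n")), delim = delim,
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("residue", "energy") %in% names(tbl))) {
    abort(sprintf("%s: expected columns `residue`, `energy`.", path))
  }
  if (anyDuplicated(tbl$residue)) {
    abort(sprintf("%s: duplicated residue label(s).", path))
  }
  tibble::tibble(ligand = ligand_id, residue = tbl$residue,
                 energy = as.numeric(tbl$energy))
}

#' Summarize and compare per-residue contribution profiles
#'
#' For each ligand, residues contributing more than `+threshold` kJ/mol
#' are called unfavorable (they oppose binding; typically polar
#' residues against a hydrophobic ligand) and those below `-threshold`
#' favorable. Profiles over different residue sets are overlaid on the
#' union, with missing residues treated as absent (no call) and noted.
#'
#' @param profiles A long tibble (`ligand`, `residue`, `energy`) — e.g.
#'   several [read_residue_profile()] results bound together — or a
#'   list of such tibbles.
#' @param threshold Call threshold in kJ/mol (>= 0).
#' @return A list with `calls` (per ligand-residue: energy and call),
#'   `counts` (per ligand: favorable/unfavorable/neutral/total), and
#'   `overlay` (residues x ligands wide energy table). If residue
#'   universes differ, attribute `residue_universe_note` records it.
#' @export
residue_profile_summary <- function(profiles, threshold = 1) {
  stopifnot(threshold >= 0)
  if (!is.data.frame(profiles)) profiles <- dplyr::bind_rows(profiles)
  if (nrow(profiles) == 0) abort("need at least one profile.")
  calls <- profiles |>
    dplyr::mutate(call = dplyr::case_when(
      .data$energy > threshold ~ "unfavorable",
      .data$energy < -threshold ~ "favorable",
      .default = "neutral"
    ))
  counts <- calls |>
    dplyr::count(.data$ligand, .data$call) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n",
                       values_fill = 0L)
  for (col in c("favorable", "unfavorable", "neutral")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    dplyr::mutate(total = .data$favorable + .data$unfavorable +
                    .data$neutral) |>
    dplyr::select("ligand", "favorable", "unfavorable", "neutral", "total")
  overlay <- calls |>
    dplyr::select("ligand", "residue", "energy") |>
    tidyr::pivot_wider(names_from = "ligand", values_from = "energy")
  universes <- split(profiles$residue, profiles$ligand)
  note <- NULL
  if (length(universes) > 1 &&
      length(unique(lapply(universes, sort))) > 1) {
    note <- "residue universes differ between ligands; overlay uses their union with missing values absent."
  }
  out <- list(calls = calls, counts = counts, overlay = overlay)
  attr(out, "residue_universe_note") <- note
  out
}

#' Full energy-table report
#'
#' Convenience wrapper: parses the table, checks the component-sum
#' identity, ranks ligands, and (optionally) summarizes per-residue
#' profiles.
#'
#' @param table_path Path to the decomposition table.
#' @param residue_paths Optional named character vector of per-residue
#'   profile files (names = ligand ids).
#' @param tol Sum-identity tolerance, kJ/mol.
#' @param threshold Per-residue call threshold, kJ/mol.
#' @return A list `table`, `sums`, `ranking`, and `residues` (NULL if
#'   no profiles given).
#' @export
energy_report <- function(table_path, residue_paths = NULL, tol = 0.02,
                          threshold = 1) {
  tbl <- read_energy_table(table_path)
  residues <- NULL
  if (!is.null(residue_paths)) {
    profs <- purrr::imap(residue_paths, ~ read_residue_profile(.x, .y)) |>
      dplyr::bind_rows()
    residues <- residue_profile_summary(profs, threshold)
  }
  list(table = tbl, sums = validate_sums(tbl, tol),
       ranking = rank_by_binding(tbl), residues = residues)
}
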