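test_that("the MM-PBSA table parses with typographic minus signs", {
  tbl <- read_energy_table(energy_fixture())
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$mean_binding[tbl$ligand == "beta-caryophyllene"], -88.46)
  expect_equal(tbl$vdw[tbl$ligand == "verapamil"], -212.66)
})

test_that("malformed energy tables raise addressed schema errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_energy_table(empty), "schema error")
  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\tvdw\telectrostatic\tpolar_solvation\tsasa",
               "x\t1\t2\t3\t4"), missing_col)
  expect_error(read_energy_table(missing_col), "mean_binding")
  non_numeric <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\tvdw\telectrostatic\tpolar_solvation\tsasa\tmean_binding",
               "x\t1\t2\t3\t4\t10",
               "y\t1\toops\t3\t4\t8"), non_numeric)
  expect_error(read_energy_table(non_numeric), "row 2, column `electrostatic`")
})

test_that("component sums reconcile with the mean binding energy", {
  tbl <- read_energy_table(energy_fixture())
  rep_ <- validate_sums(tbl, tol = 0.02)
  # all four published rows carry only the 2-decimal rounding residual
  expect_true(all(rep_$pass))
  expect_true(all(rep_$residual <= 0.011))
  # beta-caryophyllene: -108.27 - 0.22 + 32.02 - 12.00 = -88.47 vs -88.46
  bcp <- rep_[rep_$ligand == "beta-caryophyllene", ]
  expect_equal(bcp$residual, 0.01)
  # a perturbed total fails
  tbl2 <- tbl
  tbl2$mean_binding[1] <- tbl2$mean_binding[1] + 1.0
  expect_false(validate_sums(tbl2)$pass[1])
  # invariant to row order and sign encoding (already normalized on read)
  expect_equal(dplyr::arrange(validate_sums(tbl[4:1, ]), ligand),
               dplyr::arrange(rep_, ligand))
})

test_that("ligands rank by affinity, most negative binding first", {
  tbl <- read_energy_table(energy_fixture())
  rk <- rank_by_binding(tbl)
  expect_equal(rk$ligand,
               c("verapamil", "beta-caryophyllene",
                 "beta-caryophyllene oxide", "alpha-caryophyllene"))
  expect_false(any(rk$tied))
  # permutation: nothing lost or duplicated
  expect_setequal(rk$ligand, tbl$ligand)
  # ties break alphabetically and are flagged
  tie <- tibble::tibble(ligand = c("b", "a"), vdw = 0, electrostatic = 0,
                        polar_solvation = 0, sasa = 0, mean_binding = -5)
  rk2 <- rank_by_binding(tie)
  expect_equal(rk2$ligand, c("a", "b"))
  expect_true(all(rk2$tied))
  single <- rank_by_binding(tbl[2, ])
  expect_equal(single$ligand, "beta-caryophyllene")
})

test_that("residue profiles classify favorable and unfavorable contacts", {
  ver <- read_residue_profile(
    system.file("extdata", "residue_contributions_synthetic_verapamil.tsv",
                package = "metrosyn"), "verapamil")
  # the strongly positive Glu223 contact (+16.3 kJ/mol) is unfavorable
  summ <- residue_profile_summary(ver, threshold = 1)
  unfav <- summ$calls$residue[summ$calls$call == "unfavorable"]
  expect_true("Glu223" %in% unfav)
  expect_equal(summ$calls$energy[summ$calls$residue == "Glu223"], 16.3)
  # an all-zero profile yields no calls
  flat <- tibble::tibble(ligand = "x", residue = paste0("R", 1:5), energy = 0)
  s0 <- residue_profile_summary(flat, threshold = 1)
  expect_equal(s0$counts$favorable + s0$counts$unfavorable, 0L)
  # counts always partition the residues
  expect_true(all(with(s0$counts, favorable + unfavorable + neutral == total)))
  expect_true(all(with(summ$counts, favorable + unfavorable + neutral == total)))
})

test_that("uniformly stronger binding yields at least as many favorable calls", {
  withr::with_seed(7, {
    res <- paste0("R", 1:20)
    b <- tibble::tibble(ligand = "B", residue = res,
                        energy = rnorm(20, 0, 3))
    a <- tibble::tibble(ligand = "A", residue = res,
                        energy = b$energy - runif(20, 0.5, 2))
    s <- residue_profile_summary(dplyr::bind_rows(a, b), threshold = 1)
    cf <- setNames(s$counts$favorable, s$counts$ligand)
    expect_gte(cf[["A"]], cf[["B"]])
  })
})

test_that("mismatched residue universes overlay on their union with a note", {
  a <- tibble::tibble(ligand = "A", residue = c("R1", "R2"), energy = c(-2, 3))
  b <- tibble::tibble(ligand = "B", residue = c("R2", "R3"), energy = c(1, -4))
  s <- residue_profile_summary(dplyr::bind_rows(a, b))
  expect_equal(nrow(s$overlay), 3)
  expect_match(attr(s, "residue_universe_note"), "union")
})

test_that("energy_report bundles parsing, sums, ranking and residues", {
  rep_ <- energy_report(
    energy_fixture(),
    residue_paths = c(verapamil = system.file(
      "extdata", "residue_contributions_synthetic_verapamil.tsv",
      package = "metrosyn")))
  expect_true(all(rep_$sums$pass))
  expect_equal(rep_$ranking$ligand[1], "verapamil")
  expect_false(is.null(rep_$residues))
})
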