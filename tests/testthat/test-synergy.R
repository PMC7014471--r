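test_that("reversal ratio reproduces the published worked examples", {
  expect_equal(reversal_ratio(14.4, 1.0), 14.4)
  expect_equal(round(reversal_ratio(14.4, 3.4), 1), 4.2)
  expect_equal(reversal_ratio(7, 7), 1.0)
  expect_error(reversal_ratio(14.4, 0), "positive")
  # exact inverse property
  withr::with_seed(4, {
    a <- 10^runif(20, -1, 2); b <- 10^runif(20, -1, 2)
    expect_equal(reversal_ratio(a, b) * b, a)
  })
})

test_that("combination index reproduces the published worked examples", {
  expect_equal(round(ci_value(8.6, 14.4, 50, 197.0), 2), 0.85)
  expect_equal(round(ci_value(1.0, 14.4, 100, 197.0), 2), 0.58)
  # null modulator: combo equals drug alone -> CI 1
  expect_equal(ci_value(14.4, 14.4, 0, 197.0), 1.0)
  expect_error(ci_value(1, 0, 50, 197), "> 0")
})

test_that("combination index is monotone in each argument", {
  base <- ci_value(5, 10, 50, 200)
  expect_gt(ci_value(6, 10, 50, 200), base)   # increasing in combo IC50
  expect_gt(ci_value(5, 10, 60, 200), base)   # increasing in modulator dose
  expect_lt(ci_value(5, 12, 50, 200), base)   # decreasing in drug-alone IC50
  expect_lt(ci_value(5, 10, 50, 240), base)   # decreasing in modulator IC50
})

test_that("interaction classification honors the additivity band", {
  expect_identical(classify_interaction(0.58), "synergistic")
  expect_identical(classify_interaction(1.02), "additive")
  expect_identical(classify_interaction(1.3), "antagonistic")
  expect_identical(classify_interaction(0.96, additive_band = 0.05),
                   "additive")
  expect_identical(classify_interaction(0.96, additive_band = 0),
                   "synergistic")
  expect_error(classify_interaction(-1), "> 0")
})

test_that("point_side uses the normalized dose sum", {
  line <- list(c(14.4, 0), c(0, 197))
  expect_identical(point_side(c(0, 0), line), "below")
  expect_identical(point_side(c(14.4, 197), line), "above")
  expect_identical(point_side(c(7.2, 98.5), line), "on")
  # normalized sum 0.9 + 0.2 = 1.1 -> above the line
  expect_identical(point_side(c(14.4 * 0.9, 197 * 0.2), line), "above")
  expect_error(point_side(c(1, 1), list(c(1, 0), c(1, 0))), "distinct")
})

test_that("isobologram geometry agrees with the CI statistic", {
  # point exactly on the additivity line: CI = 1.00
  exp_on <- combination_experiment(14.4, 197, 98.5, 7.2, "24h")
  res_on <- isobologram(exp_on)
  expect_identical(res_on$point_side, "on")
  expect_equal(round(res_on$ci, 2), 1.00)
  # published 24 h + 50 uM beta-caryophyllene: below the line, synergistic
  exp_bcp <- combination_experiment(14.4, 197.0, 50, 8.6, "24h")
  res_bcp <- isobologram(exp_bcp)
  expect_identical(res_bcp$point_side, "below")
  expect_identical(res_bcp$interaction, "synergistic")
  expect_equal(round(res_bcp$ci, 2), 0.85)
  expect_equal(round(res_bcp$rr, 1), 1.7)
  td <- tidy(res_bcp)
  expect_equal(td$ci, res_bcp$ci)
})

test_that("classification and geometric side are the same statistic", {
  withr::with_seed(99, {
    for (i in 1:200) {
      ic_a <- 10^runif(1, -1, 2); ic_b <- 10^runif(1, 0, 3)
      c_a <- 10^runif(1, -2, 2); c_b <- runif(1, 0.01, ic_b * 0.99)
      ci <- ci_value(c_a, ic_a, c_b, ic_b)
      side <- point_side(c(c_a, c_b), list(c(ic_a, 0), c(0, ic_b)))
      expected <- c(below = "synergistic", on = "additive",
                    above = "antagonistic")[[side]]
      expect_identical(classify_interaction(ci, additive_band = 0), expected)
    }
  })
})

test_that("the connection curve is decorative and failure-tolerant", {
  exp_bcp <- combination_experiment(14.4, 197.0, 50, 8.6, "24h")
  res <- isobologram(exp_bcp)
  if (isTRUE(res$curve_converged)) {
    cc <- res$connection_curve
    # the fitted exponential passes near the modulator-axis intercept
    expect_equal(unname(cc[["top"]]), 197, tolerance = 0.15)
  }
  # classification never depends on the curve
  expect_identical(res$interaction, "synergistic")
})

test_that("synergy_table scores combinations under the same-schedule rule", {
  fits <- tibble::tibble(
    compound = c("doxorubicin", "beta_caryophyllene", "doxorubicin"),
    modulator = c(NA, NA, "beta_caryophyllene"),
    modulator_conc_uM = c(0, 0, 50),
    schedule = "24h",
    ic50 = c(14.4, 197.0, 8.6)
  )
  design <- tibble::tibble(drug = "doxorubicin",
                           modulator = "beta_caryophyllene",
                           modulator_conc_uM = 50, schedule = "24h")
  out <- synergy_table(fits, design)
  expect_equal(nrow(out), 1)
  expect_equal(round(out$ci, 2), 0.85)
  expect_equal(round(out$rr, 1), 1.7)
  expect_identical(out$interaction, "synergistic")
  # a missing alone fit is a specific, addressed error
  expect_error(synergy_table(fits[-2, ], design), "exactly one fit")
})
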