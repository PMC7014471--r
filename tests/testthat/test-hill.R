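test_that("hill_response satisfies the half-maximal identity and limits", {
  # at conc = IC50 the response is exactly emax/2, whatever the other pars
  for (emax in c(50, 88, 100)) {
    for (slope in c(0.5, 1, 2.7)) {
      expect_equal(hill_response(14.4, emax, log10(14.4), slope), emax / 2)
    }
  }
  expect_equal(hill_response(14.4, 88, log10(14.4), 1), 44.0)
  # hand-evaluated: 100 / (1 + (10/100)^2)
  expect_equal(hill_response(100, 100, 1, 2), 100 / (1 + 0.1^2),
               tolerance = 1e-12)
  # zero concentration is the limit 0, not an error
  expect_identical(hill_response(0, 88, 1, 1.2), 0)
  expect_error(hill_response(-1, 88, 1, 1.2), "non-negative")
  expect_error(hill_response(10, 88, 1, -2), "hill_slope")
})

test_that("hill_response is monotone increasing in concentration", {
  withr::with_seed(11, {
    for (i in 1:25) {
      emax <- runif(1, 50, 100)
      lic <- runif(1, log10(0.5), log10(400))
      slope <- runif(1, 0.5, 3)
      conc <- sort(10^runif(20, -2, 3))
      resp <- hill_response(conc, emax, lic, slope)
      expect_true(all(diff(resp) > 0))
      expect_lt(max(resp), emax)
    }
  })
})

test_that("fit_hill recovers noiseless generating parameters", {
  # round-trip at <= 0.1% relative error across the plausible ranges
  cases <- expand.grid(emax = c(55, 88, 100), ic50 = c(0.5, 14.4, 400),
                       slope = c(0.5, 1.2, 3))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    conc <- cs$ic50 * c(1 / 27, 1 / 9, 1 / 3, 0.7, 1.5, 3, 9, 27)
    d <- make_hill_data(cs$emax, cs$ic50, cs$slope, conc = conc, reps = 1)
    f <- fit_hill(d)
    expect_true(f$converged)
    expect_equal(f$ic50, cs$ic50, tolerance = 1e-3)
    expect_equal(f$emax, cs$emax, tolerance = 1e-3)
    expect_equal(f$hill_slope, cs$slope, tolerance = 1e-3)
  }
})

test_that("fit_hill rejects degenerate inputs", {
  flat <- tibble::tibble(conc = c(1, 2, 5, 10), inhibition = 0)
  expect_error(fit_hill(flat), "no dose effect")
  few <- make_hill_data(conc = c(1, 10, 100))
  expect_error(fit_hill(few), ">= 4 distinct")
  bad <- tibble::tibble(conc = c(1, 2, 5, 10), inhibition = c(1, 2, NA, 4))
  expect_error(fit_hill(bad), "finite")
})

test_that("robust soft-L1 loss resists an outlier well", {
  d <- make_hill_data(88, 14.4, 1.2, reps = 3)
  d$inhibition[5] <- d$inhibition[5] + 60 # one wild well
  f_ls <- fit_hill(d, fit_options())
  f_rb <- fit_hill(d, fit_options(loss = "robust_soft_l1"))
  expect_true(f_rb$converged)
  expect_lt(abs(f_rb$ic50 - 14.4), abs(f_ls$ic50 - 14.4))
})

test_that("emax can be fixed", {
  d <- make_hill_data(100, 10, 1, reps = 1)
  f <- fit_hill(d, fit_options(fix_emax_at = 100))
  expect_equal(f$emax, 100)
  expect_equal(f$ic50, 10, tolerance = 1e-4)
})

test_that("ic50_confidence collapses on noiseless data and is reproducible", {
  d <- make_hill_data(88, 14.4, 1.2, reps = 3)
  f <- fit_hill(d)
  fb <- ic50_confidence(d, f, fit_options(n_boot = 100, seed = 5))
  expect_identical(fb$cl_method, "bootstrap")
  # zero residuals: every resample refits the same curve
  expect_equal(unname(fb$ic50_cl[["lower"]]), fb$ic50, tolerance = 1e-6)
  expect_equal(unname(fb$ic50_cl[["upper"]]), fb$ic50, tolerance = 1e-6)
  # determinism under a fixed seed
  d2 <- make_hill_data(88, 14.4, 1.2, reps = 3, sd = 6, seed = 3)
  f2 <- fit_hill(d2)
  a <- ic50_confidence(d2, f2, fit_options(n_boot = 50, seed = 9))
  b <- ic50_confidence(d2, f2, fit_options(n_boot = 50, seed = 9))
  expect_identical(a$ic50_cl, b$ic50_cl)
  # n_boot = 0 falls back to the asymptotic Wald interval
  fw <- ic50_confidence(d2, f2, fit_options(n_boot = 0))
  expect_identical(fw$cl_method, "asymptotic")
  expect_true(fw$ic50_cl[["lower"]] <= fw$ic50 &&
                fw$ic50 <= fw$ic50_cl[["upper"]])
})

test_that("bootstrap interval width does not shrink as noise grows", {
  widths <- sapply(c(3, 12), function(sd) {
    ws <- sapply(1:5, function(s) {
      d <- make_hill_data(88, 14.4, 1.2, reps = 3, sd = sd, seed = s)
      f <- fit_hill(d)
      fb <- ic50_confidence(d, f, fit_options(n_boot = 60, seed = s))
      log(fb$ic50_cl[["upper"]] / fb$ic50_cl[["lower"]])
    })
    median(ws)
  })
  expect_gte(widths[2], widths[1])
})

test_that("fold_potency_change divides reference by alternative IC50", {
  expect_equal(fold_potency_change(14.4, 1.6), 9.0)
  expect_equal(round(fold_potency_change(13.6, 11.6), 1), 1.2)
  d <- make_hill_data(88, 10, 1, reps = 1)
  f <- fit_hill(d)
  expect_equal(fold_potency_change(f, f), 1.0)
  expect_error(fold_potency_change(0, 1), "positive")
})

test_that("cytotoxicity threshold is strict at 70% viability", {
  expect_true(classify_cytotoxic(69.9))
  expect_false(classify_cytotoxic(70.0))
  expect_true(classify_cytotoxic(12.0)) # ~88% inhibition
  expect_error(classify_cytotoxic(NA_real_), "finite")
})

test_that("molar-mass conversion round-trips", {
  mm <- reference_molar_mass()
  x <- c(1, 14.4, 100)
  expect_equal(convert_conc(convert_conc(x, mm[["doxorubicin"]], "uM"),
                            mm[["doxorubicin"]], "ug_ml"), x)
  # 100 uM doxorubicin HCl is ~58 ug/mL (the assay's 0.5-50 ug/mL range
  # maps to ~1-100 uM)
  expect_equal(convert_conc(100, mm[["doxorubicin"]], "uM"), 57.998)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- make_hill_data(88, 14.4, 1.2, reps = 2)
  f <- fit_hill(d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("emax", "log_ic50", "hill_slope"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$ic50, 10^td$estimate[td$term == "log_ic50"])
})
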