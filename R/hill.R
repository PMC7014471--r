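#' Hill concentration-response model
#'
#' Predicted percent inhibition at concentration `conc` under the
#' three-parameter inhibitory Hill model
#' \deqn{E = E_{max} / \left[1 + (10^{\log IC_{50}} / A)^{h}\right]}
#' where `A` is the concentration, `emax` the maximal inhibition (%),
#' `log_ic50` the base-10 log of the half-maximal concentration and
#' `hill_slope` (`h`) the steepness. The curve passes through
#' `emax / 2` exactly at `conc = 10^log_ic50` and tends to 0 as
#' `conc -> 0` (the zero-concentration limit is returned, not an error).
#'
#' @param conc Concentration(s), in µM; must be finite and >= 0.
#' @param emax Maximal inhibition, percent, in (0, 120].
#' @param log_ic50 log10 of the IC50 in µM.
#' @param hill_slope Dimensionless slope; must be > 0 for an inhibitory
#'   response.
#' @return Numeric vector of percent inhibition, same length as `conc`.
#' @examples
#' hill_response(14.4, emax = 88, log_ic50 = log10(14.4), hill_slope = 1)
#' @export
hill_response <- function(conc, emax, log_ic50, hill_slope) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("`conc` must be finite and non-negative.")
  }
  if (hill_slope <= 0) abort("`hill_slope` must be > 0 for inhibition curves.")
  out <- numeric(length(conc))
  pos <- conc > 0
  # evaluated on the log scale: 1 + 10^(h * (logIC50 - log10 A)) is stable
  # for concentrations many decades from the IC50
  out[pos] <- emax / (1 + 10^(hill_slope * (log_ic50 - log10(conc[pos]))))
  out
}

#' Fitting options for Hill concentration-response fits
#'
#' @param fix_emax_at Percent, or `NULL` (default) to estimate `emax`
#'   freely with an upper bound of 120% (plate noise can push apparent
#'   inhibition nominally above 100%).
#' @param loss `"least_squares"` (default) or `"robust_soft_l1"`
#'   (smooth-L1 objective, downweights outlier wells).
#' @param n_boot Number of bootstrap resamples for IC50 confidence
#'   limits; `0` selects the asymptotic Wald interval.
#' @param seed Integer seed governing bootstrap resampling.
#' @param max_iter Maximum optimizer iterations.
#' @param bounds Named list of `c(lo, hi)` per parameter
#'   (`emax`, `log_ic50`, `hill_slope`) overriding the defaults.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(fix_emax_at = NULL,
                        loss = c("least_squares", "robust_soft_l1"),
                        n_boot = 1000L,
                        seed = 1L,
                        max_iter = 200L,
                        bounds = NULL) {
  loss <- match.arg(loss)
  stopifnot(n_boot >= 0, max_iter >= 1)
  if (!is.null(fix_emax_at) && (fix_emax_at <= 0 || fix_emax_at > 120)) {
    abort("`fix_emax_at` must lie in (0, 120].")
  }
  default_bounds <- list(
    emax       = c(1e-3, 120),
    log_ic50   = c(-6, 6),
    hill_slope = c(0.05, 10)
  )
  if (!is.null(bounds)) {
    for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]
  }
  structure(
    list(
      fix_emax_at = fix_emax_at, loss = loss, n_boot = as.integer(n_boot),
      seed = as.integer(seed), max_iter = as.integer(max_iter),
      bounds = default_bounds
    ),
    class = "fit_options"
  )
}

# starting values from the data: emax near the top of the response,
# log_ic50 at the interpolated half-maximal concentration, unit slope
hill_start <- function(conc, resp, opts) {
  emax0 <- if (!is.null(opts$fix_emax_at)) opts$fix_emax_at else
    min(max(max(resp), 10), 119)
  half <- emax0 / 2
  ord <- order(conc)
  cs <- conc[ord]; rs <- resp[ord]
  above <- which(rs >= half)
  lic0 <- if (length(above) == 0) {
    log10(max(cs))
  } else if (min(above) == 1) {
    log10(min(cs))
  } else {
    i <- min(above)
    # linear interpolation on log-concentration between bracketing doses
    f <- (half - rs[i - 1]) / max(rs[i] - rs[i - 1], 1e-9)
    log10(cs[i - 1]) + f * (log10(cs[i]) - log10(cs[i - 1]))
  }
  c(emax = emax0, log_ic50 = lic0, hill_slope = 1)
}

clamp <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])

#' Fit the Hill model to concentration-inhibition data
#'
#' Estimates `(emax, log_ic50, hill_slope)` by Levenberg-Marquardt
#' nonlinear least squares (or a smooth-L1 robust objective) on
#' well-level points. Fitting is performed against log10 concentration;
#' zero-concentration (vehicle) rows are excluded — they enter only via
#' normalization — because the Hill form is undefined at zero dose.
#'
#' @param data Data frame with columns `conc` (µM) and `inhibition`
#'   (percent), one row per well. At least 4 distinct non-zero
#'   concentrations are required.
#' @param options A [fit_options()] list.
#' @return An object of class `hill_fit`: estimates, `ic50 = 10^log_ic50`,
#'   asymptotic confidence limits (see [ic50_confidence()] for bootstrap
#'   limits), residual sum of squares, convergence flag, and the data
#'   used, accessible via [generics::tidy()] / [generics::glance()].
#' @examples
#' d <- tibble::tibble(conc = c(1, 2, 5, 10, 20, 50, 100))
#' d$inhibition <- hill_response(d$conc, 88, log10(14.4), 1.2)
#' fit <- fit_hill(d)
#' glance(fit)$ic50
#' @export
fit_hill <- function(data, options = fit_options()) {
  stopifnot(is.data.frame(data))
  if (!all(c("conc", "inhibition") %in% names(data))) {
    abort("`data` must have columns `conc` and `inhibition`.")
  }
  d <- dplyr::filter(data, .data$conc > 0)
  if (any(!is.finite(d$inhibition))) abort("responses must be finite.")
  if (dplyr::n_distinct(d$conc) < 4) {
    abort("need >= 4 distinct non-zero concentrations to fit a Hill curve.")
  }
  if (all(abs(d$inhibition) < 1e-9)) {
    abort("no dose effect: all responses are zero.")
  }
  start <- hill_start(d$conc, d$inhibition, options)
  fit <- hill_optimize(d$conc, d$inhibition, start, options)
  structure(
    c(fit,
      list(
        ic50 = 10^fit$log_ic50,
        ic50_cl = asymptotic_cl(fit),
        cl_method = "asymptotic",
        n_points = nrow(d),
        data = tibble::as_tibble(d[c("conc", "inhibition")]),
        options = options
      )),
    class = "hill_fit"
  )
}

# single optimizer pass; returns estimates, rss, convergence, vcov
hill_optimize <- function(conc, resp, start, opts) {
  b <- opts$bounds
  fixed_emax <- opts$fix_emax_at
  lconc <- log10(conc)
  if (opts$loss == "least_squares") {
    model <- if (is.null(fixed_emax)) {
      inhibition ~ emax / (1 + 10^(hill_slope * (log_ic50 - lconc)))
    } else {
      inhibition ~ emax0 / (1 + 10^(hill_slope * (log_ic50 - lconc)))
    }
    df <- data.frame(inhibition = resp, lconc = lconc)
    if (!is.null(fixed_emax)) df$emax0 <- fixed_emax
    pars <- c("emax", "log_ic50", "hill_slope")
    if (!is.null(fixed_emax)) pars <- c("log_ic50", "hill_slope")
    lower <- vapply(pars, function(p) b[[p]][1], 0)
    upper <- vapply(pars, function(p) b[[p]][2], 0)
    st <- clamp(start[pars], c(-Inf, Inf))
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        model, data = df, start = as.list(st),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = opts$max_iter)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(list(
        emax = NA_real_, log_ic50 = NA_real_, hill_slope = NA_real_,
        rss = NA_real_, converged = FALSE, vcov = NULL,
        diagnostics = conditionMessage(fit)
      ))
    }
    cf <- coef(fit)
    if (!is.null(fixed_emax)) cf <- c(emax = fixed_emax, cf)
    vc <- tryCatch(vcov(fit), error = function(e) NULL)
    # expand vcov to full parameter order when emax is fixed
    list(
      emax = unname(cf["emax"]), log_ic50 = unname(cf["log_ic50"]),
      hill_slope = unname(cf["hill_slope"]),
      rss = sum(stats::resid(fit)^2), converged = TRUE, vcov = vc,
      diagnostics = NULL
    )
  } else {
    # robust smooth-L1: rho(r) = 2 (sqrt(1 + r^2) - 1)
    pars <- if (is.null(fixed_emax)) c("emax", "log_ic50", "hill_slope") else
      c("log_ic50", "hill_slope")
    obj <- function(p) {
      p <- setNames(p, pars)
      emax <- if (is.null(fixed_emax)) p["emax"] else fixed_emax
      pred <- emax / (1 + 10^(p["hill_slope"] * (p["log_ic50"] - lconc)))
      sum(2 * (sqrt(1 + (resp - pred)^2) - 1))
    }
    lower <- vapply(pars, function(p) b[[p]][1], 0)
    upper <- vapply(pars, function(p) b[[p]][2], 0)
    st <- pmin(pmax(start[pars], lower), upper)
    res <- stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(maxit = opts$max_iter))
    cf <- setNames(res$par, pars)
    if (!is.null(fixed_emax)) cf <- c(emax = fixed_emax, cf)
    pred <- cf["emax"] / (1 + 10^(cf["hill_slope"] * (cf["log_ic50"] - lconc)))
    list(
      emax = unname(cf["emax"]), log_ic50 = unname(cf["log_ic50"]),
      hill_slope = unname(cf["hill_slope"]),
      rss = sum((resp - pred)^2), converged = res$convergence == 0,
      vcov = NULL, diagnostics = if (res$convergence != 0) res$message
    )
  }
}

# Wald interval on log_ic50, back-transformed to µM
asymptotic_cl <- function(fit) {
  if (!isTRUE(fit$converged) || is.null(fit$vcov) ||
      !"log_ic50" %in% rownames(fit$vcov)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  se <- sqrt(max(fit$vcov["log_ic50", "log_ic50"], 0))
  c(lower = 10^(fit$log_ic50 - qnorm(0.975) * se),
    upper = 10^(fit$log_ic50 + qnorm(0.975) * se))
}

#' Confidence limits for a fitted IC50
#'
#' Nonparametric bootstrap (the default): wells are resampled with
#' replacement within each concentration, the Hill model is refitted,
#' and the 2.5/97.5 percentiles of the resampled IC50s are returned.
#' With `options$n_boot = 0` the asymptotic Wald interval on
#' `log_ic50`, back-transformed to µM, is returned instead. Bootstrap
#' resampling is deterministic given `options$seed`.
#'
#' @param data The well-level data frame the fit was computed from
#'   (columns `conc`, `inhibition`).
#' @param fit A converged `hill_fit`.
#' @param options A [fit_options()]; `n_boot` and `seed` control the
#'   bootstrap.
#' @return The `hill_fit` with `ic50_cl` and `cl_method` updated.
#'   More than 20% failed bootstrap refits is an error.
#' @export
ic50_confidence <- function(data, fit, options = fit$options) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) abort("cannot compute limits for a non-converged fit.")
  if (options$n_boot == 0) {
    fit$ic50_cl <- asymptotic_cl(fit)
    fit$cl_method <- "asymptotic"
    return(fit)
  }
  d <- dplyr::filter(data, .data$conc > 0)
  groups <- split(seq_len(nrow(d)), d$conc)
  boots <- withr::with_seed(options$seed, {
    purrr::map_dbl(seq_len(options$n_boot), function(i) {
      idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                            replace = TRUE)]))
      db <- d[idx, ]
      start <- c(emax = fit$emax, log_ic50 = fit$log_ic50,
                 hill_slope = fit$hill_slope)
      bf <- hill_optimize(db$conc, db$inhibition, start, options)
      if (isTRUE(bf$converged)) 10^bf$log_ic50 else NA_real_
    })
  })
  fail_frac <- mean(is.na(boots))
  if (fail_frac > 0.2) {
    abort(sprintf("bootstrap unstable: %.0f%% of refits failed.",
                  100 * fail_frac))
  }
  qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  fit$ic50_cl <- c(lower = min(qs[1], fit$ic50), upper = max(qs[2], fit$ic50))
  fit$cl_method <- "bootstrap"
  fit
}

#' Fold change in potency between two fits
#'
#' The ratio `ic50_ref / ic50_alt`; values > 1 mean the alternative
#' condition (longer exposure, added chemosensitizer, ...) potentiated
#' the drug.
#'
#' @param fit_ref,fit_alt Converged `hill_fit` objects, or bare IC50
#'   values in µM.
#' @return A positive scalar.
#' @export
fold_potency_change <- function(fit_ref, fit_alt) {
  ic_of <- function(x, what) {
    if (inherits(x, "hill_fit")) {
      if (!isTRUE(x$converged)) abort(paste(what, "fit has not converged."))
      x$ic50
    } else {
      as.numeric(x)
    }
  }
  a <- ic_of(fit_ref, "reference"); b <- ic_of(fit_alt, "alternative")
  if (any(!is.finite(c(a, b))) || a <= 0 || b <= 0) {
    abort("IC50 values must be positive and finite.")
  }
  a / b
}

#' Flag cytotoxic treatments
#'
#' A treatment is called cytotoxic when cell viability falls strictly
#' below 70% of the vehicle control, the conventional biological
#' relevance threshold for in vitro cytotoxicity screens.
#'
#' @param percent_viability Percent viability value(s) relative to the
#'   vehicle control.
#' @return Logical vector: `TRUE` where viability < 70%.
#' @export
classify_cytotoxic <- function(percent_viability) {
  if (any(!is.finite(percent_viability))) abort("viability must be finite.")
  percent_viability < 70
}

#' Convert between µM and µg/mL
#'
#' @param x Concentration value(s).
#' @param molar_mass Molar mass in g/mol. Masses for the compounds of
#'   the default study: doxorubicin HCl 579.98, beta-caryophyllene
#'   204.35, beta-caryophyllene oxide 220.35 g/mol.
#' @param from `"uM"` or `"ug_ml"`.
#' @return Converted concentration(s) (µg/mL if `from = "uM"`, µM
#'   otherwise).
#' @export
convert_conc <- function(x, molar_mass, from = c("uM", "ug_ml")) {
  from <- match.arg(from)
  stopifnot(molar_mass > 0)
  if (from == "uM") x * molar_mass / 1000 else x * 1000 / molar_mass
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  if (isTRUE(x$converged)) {
    cat(sprintf("  emax %.1f%%  log10(IC50) %.3f  slope %.2f\n",
                x$emax, x$log_ic50, x$hill_slope))
    cat(sprintf("  IC50 %.2f uM (%s CL %.2f-%.2f)\n", x$ic50, x$cl_method,
                x$ic50_cl[["lower"]], x$ic50_cl[["upper"]]))
    cat(sprintf("  n = %d wells, rss = %.3g\n", x$n_points, x$rss))
  } else {
    cat("  fit did not converge:", x$diagnostics %||% "", "\n")
  }
  invisible(x)
}
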