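#' Fit an acetate standard curve
#'
#' Ordinary least-squares line relating assay signal to product
#' concentration. The fitted curve converts raw fluorescence signal to uM
#' product via `(signal - intercept) / slope`.
#'
#' @param standards `data.frame` with columns `concentration` (uM) and
#'   `signal`, or a two-column matrix in that order.
#' @return an object of class `standard_curve` with fields `slope`
#'   (signal per uM), `intercept`, `r_squared`.
#' @examples
#' sc <- fit_standard_curve(data.frame(concentration = c(0, 10, 20),
#'                                     signal = c(0, 100, 200)))
#' sc$slope  # 10
#' @export
fit_standard_curve <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "signal") %in% names(standards))) {
    names(standards)[1:2] <- c("concentration", "signal")
  }
  conc <- standards$concentration
  assert_that(length(unique(conc)) >= 2,
              "degenerate design: need >= 2 distinct concentrations")
  fit <- stats::lm(signal ~ concentration, data = standards)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(standards$signal) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, n = nrow(standards)),
            class = "standard_curve")
}

#' @rdname fit_standard_curve
#' @param curve a `standard_curve`.
#' @param signal numeric vector of raw signals.
#' @return `convert_signal()` returns product concentrations in uM.
#' @export
convert_signal <- function(curve, signal) {
  (signal - curve$intercept) / curve$slope
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: signal = %.4g * [uM] + %.4g (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Initial velocity from a deacetylation time course
#'
#' The initial velocity at one substrate concentration is the slope of an
#' OLS line through the early, linear portion of the progress curve.
#' Timepoints are retained while product stays at or below
#' `max_conversion` of the substrate concentration (default 10%), after
#' which substrate depletion bends the curve.
#'
#' @param tc a time-course `data.frame` with columns `time_s` (seconds,
#'   strictly increasing) and `product_uM`, plus attributes or columns
#'   `substrate_conc` and `enzyme_conc` (uM).
#' @param max_conversion maximum allowed fraction of substrate converted.
#' @return a one-row `data.frame` (velocity point) with `substrate_conc`,
#'   `v0` (uM/s), `stderr`, `n_used`.
#' @export
initial_velocity <- function(tc, max_conversion = 0.10) {
  s_conc <- tc$substrate_conc[1] %||% attr(tc, "substrate_conc")
  assert_that(is_number(s_conc), "time course must carry substrate_conc")
  assert_that(nrow(tc) >= 3, "insufficient data: need >= 3 timepoints")
  assert_that(all(diff(tc$time_s) > 0), "times must be strictly increasing")
  keep <- tc$product_uM <= max_conversion * s_conc
  assert_that(sum(keep) >= 3,
              "insufficient data: fewer than 3 timepoints below %.0f%% conversion",
              100 * max_conversion)
  sub <- tc[keep, ]
  fit <- stats::lm(product_uM ~ time_s, data = sub)
  # noiseless synthetic courses fit exactly; the perfect-fit warning from
  # summary.lm is expected there and carries no information
  se <- suppressWarnings(summary(fit)$coefficients["time_s", "Std. Error"])
  data.frame(substrate_conc = s_conc,
             v0 = unname(stats::coef(fit)[2]),
             stderr = se,
             n_used = sum(keep))
}

#' Fit the Michaelis-Menten equation to initial velocities
#'
#' Unweighted nonlinear least squares of the per-enzyme velocity against
#' substrate concentration,
#' `v0/[E] = (kcat/KM) * [S] / ([S]/KM + 1)` (equivalently
#' `kcat*[S]/(KM+[S])`), giving the turnover number `kcat` (s^-1), the
#' Michaelis constant `KM` (uM) and the catalytic efficiency kcat/KM
#' (M^-1 s^-1). When the fitted KM falls below the assay detection limit
#' (~10-20 uM substrate for the acetate assay) only a lower bound on
#' kcat/KM is reportable; the fit is then flagged `capped` and the bound
#' is computed at `km = detection_limit`.
#'
#' Initialization uses `kcat0 = max(v0)/[E]`, `KM0 = median([S])`, with up
#' to 5 multiplicative-perturbation restarts on non-convergence.
#'
#' @param points velocity points, a `data.frame` with columns
#'   `substrate_conc` (uM) and `v0` (uM/s); see [initial_velocity()].
#' @param enzyme_conc enzyme concentration in uM.
#' @param detection_limit KM detection limit in uM (default 20, the upper
#'   end of the assay's 10-20 uM range).
#' @param weighted weight points by `1/stderr^2` when a `stderr` column is
#'   present (default `FALSE`, matching common practice).
#' @return an object of class `kinetic_fit`: `kcat`, `km`, `kcat_over_km`,
#'   their `*_se` standard errors (asymptotic, from the NLS Jacobian;
#'   efficiency SE by error propagation), `capped`, `detection_limit`,
#'   `n_points`, `quality_flags`.
#' @examples
#' s <- c(5, 10, 25, 50, 100, 250)
#' v <- 4.2 * 0.5 * s / (19 + s)     # kcat 4.2/s, KM 19 uM, [E] 0.5 uM
#' fit <- fit_michaelis_menten(data.frame(substrate_conc = s, v0 = v), 0.5)
#' signif(fit$kcat_over_km, 2)        # 220000
#' @export
fit_michaelis_menten <- function(points, enzyme_conc, detection_limit = 20,
                                 weighted = FALSE) {
  points <- as.data.frame(points)
  assert_that(is_number(enzyme_conc) && enzyme_conc > 0,
              "enzyme_conc must be a positive number")
  assert_that(nrow(points) >= 4,
              "need >= 4 substrate concentrations for a reliable fit")
  s <- points$substrate_conc
  y <- points$v0 / enzyme_conc
  w <- if (weighted && !is.null(points$stderr)) {
    (enzyme_conc / points$stderr)^2
  } else {
    rep(1, length(y))
  }
  start <- list(kcat = max(y), km = stats::median(s))
  # deterministic multiplicative perturbations keep the fit a pure function
  perturb <- list(c(1, 1), c(2, 0.5), c(0.5, 2), c(4, 0.25), c(0.25, 4), c(8, 0.125))
  fit <- NULL
  for (try in 0:5) {
    fac <- perturb[[try + 1]]
    fit <- tryCatch(
      stats::nls(y ~ kcat * s / (km + s),
                 start = list(kcat = start$kcat * fac[1],
                              km = start$km * fac[2]),
                 weights = w, algorithm = "port",
                 lower = c(kcat = 1e-12, km = 1e-9),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    stop2("Michaelis-Menten fit failed after restarts: %s", conditionMessage(fit))
  }
  cf <- summary(fit)$coefficients
  kcat <- cf["kcat", "Estimate"]; kcat_se <- cf["kcat", "Std. Error"]
  km <- cf["km", "Estimate"];     km_se <- cf["km", "Std. Error"]
  capped <- km < detection_limit
  km_eff <- if (capped) detection_limit else km
  eff <- 1e6 * kcat / km_eff
  eff_se <- if (capped) NA_real_ else
    eff * sqrt((kcat_se / kcat)^2 + (km_se / km)^2)
  flags <- character(0)
  if (sum(s < km) < 2) flags <- c(flags, "fewer_than_2_points_below_km")
  if (capped) flags <- c(flags, "km_below_detection_limit")
  structure(list(kcat = kcat, kcat_se = kcat_se,
                 km = km, km_se = km_se,
                 kcat_over_km = eff, kcat_over_km_se = eff_se,
                 kcat_over_km_bound = if (capped) "lower" else "exact",
                 capped = capped, detection_limit = detection_limit,
                 n_points = length(y), quality_flags = flags),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  bound <- if (x$capped) "> " else ""
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n_points))
  cat(sprintf("  kcat     = %.3g +/- %.2g s^-1\n", x$kcat, x$kcat_se))
  km_txt <- if (x$capped) sprintf("< %g (below detection limit)", x$detection_limit)
            else sprintf("%.3g +/- %.2g", x$km, x$km_se)
  cat(sprintf("  KM       = %s uM\n", km_txt))
  cat(sprintf("  kcat/KM  = %s%.3g M^-1 s^-1\n", bound, x$kcat_over_km))
  if (length(x$quality_flags))
    cat("  flags:", paste(x$quality_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Substrate classification by catalytic efficiency
#'
#' Enzymes that are catalytically effective in the cell operate at
#' kcat/KM of at least 10^4 M^-1 s^-1; that value is the default cutoff
#' separating substrates from slow/non-substrates. The boundary is
#' inclusive: exactly 10^4 classifies as substrate. A capped fit whose
#' lower bound already clears the cutoff is a substrate.
#'
#' @param activity_cutoff cutoff in M^-1 s^-1 (default `1e4`).
#' @param inclusive include the boundary (default `TRUE`).
#' @return `classification_config()` returns a config list;
#'   `classify_substrate()` returns `"substrate"` or `"non-substrate"`.
#' @export
classification_config <- function(activity_cutoff = 1e4, inclusive = TRUE) {
  assert_that(is_number(activity_cutoff) && activity_cutoff > 0,
              "activity_cutoff must be positive")
  list(activity_cutoff = activity_cutoff, inclusive = inclusive)
}

#' @rdname classification_config
#' @param fit a `kinetic_fit`, or a numeric vector of kcat/KM values
#'   (M^-1 s^-1).
#' @param cfg a [classification_config()].
#' @export
classify_substrate <- function(fit, cfg = classification_config()) {
  eff <- if (inherits(fit, "kinetic_fit")) fit$kcat_over_km else as.numeric(fit)
  assert_that(all(!is.na(eff)), "kcat/KM value (or lower bound) required")
  hit <- if (cfg$inclusive) eff >= cfg$activity_cutoff else eff > cfg$activity_cutoff
  ifelse(hit, "substrate", "non-substrate")
}

#' Read assay time courses from a TSV file
#'
#' Expected columns: `substrate_conc`, `enzyme_conc`, `time_s`, and either
#' `product_uM` or `signal` (the latter requires a standard curve for
#' conversion). Rows are grouped into one time course per substrate
#' concentration.
#'
#' @param path TSV file path.
#' @param curve optional [fit_standard_curve()] result, required when the
#'   file carries raw `signal` instead of `product_uM`.
#' @return list of time-course `data.frame`s.
#' @export
read_timecourse_table <- function(path, curve = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate_conc", "enzyme_conc", "time_s")
  assert_that(all(need %in% names(tab)), "columns %s are required",
              paste(need, collapse = ", "))
  if (is.null(tab$product_uM)) {
    assert_that(!is.null(tab$signal) && !is.null(curve),
                "either product_uM, or signal plus a standard curve, required")
    tab$product_uM <- convert_signal(curve, tab$signal)
  }
  assert_that(all(tab$product_uM >= -1e-9), "product must be non-negative")
  lapply(split(tab, tab$substrate_conc), function(d) {
    d[order(d$time_s), c("substrate_conc", "enzyme_conc", "time_s", "product_uM")]
  })
}

#' @rdname fit_michaelis_menten
#' @param fit a `kinetic_fit`.
#' @param path output path for a JSON fit report.
#' @export
write_kinetic_report <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
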