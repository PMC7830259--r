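#' Full kinetic analysis of a set of hydrolysis runs
#'
#' Runs the whole kinetic stage on one or more percent-remaining series:
#' per-temperature early-window log-linear fits and full-course
#' reversible fits, an Arrhenius regression across the accelerated
#' temperatures on the reversible forward constants, and a rate /
#' half-life table over the requested report temperatures.
#'
#' @param series_list List of [conc_series()] objects, each tagged with
#'   its temperature.
#' @param verification_C Optional temperature (degC) whose series is
#'   held out of the Arrhenius regression and used instead to compute
#'   the verification error [percent_error()] against the Arrhenius
#'   prediction.
#' @param report_temperatures_C Temperatures for the output rate table;
#'   defaults to the union of fitted and verification temperatures.
#' @param window_end Early-window end for the log-linear fits, minutes.
#' @return List of class `"hydrolysis_study_fit"`: `first_order` and
#'   `reversible` (named lists of per-temperature fits), `arrhenius`
#'   (the [fit_arrhenius()] object), `verification` (list with
#'   `temperature_C`, `k_observed`, `k_predicted`, `pct_error`, or NULL),
#'   `table` (the [rate_table()]).
#' @examples
#' b <- generate_full_study(study_design(seed = 3))
#' analyze_hydrolysis_study(b$series[1:3], verification_C = NA)
#' @export
analyze_hydrolysis_study <- function(series_list, verification_C = 20,
                                     report_temperatures_C = NULL,
                                     window_end = 10) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  temps <- vapply(series_list, function(s) attr(s, "temperature_C"), numeric(1))
  if (anyNA(temps))
    stop("every series must carry its temperature_C attribute", call. = FALSE)
  names(series_list) <- paste0("T", temps)
  is_ver <- !is.na(verification_C) & temps == verification_C
  # slow runs sampled at coarse intervals: widen the window to the first
  # 3 points so the log-linear fit is always defined
  fo <- lapply(series_list, function(s)
    fit_first_order(s, window_end = max(window_end, s$time_min[3L])))
  rv <- lapply(series_list, fit_reversible)
  kf <- vapply(rv, function(f) f$params$k_forward, numeric(1))
  if (sum(!is_ver) < 2L)
    stop("need at least 2 non-verification temperatures for the Arrhenius fit",
         call. = FALSE)
  arr <- fit_arrhenius(temps[!is_ver], kf[!is_ver])
  verification <- NULL
  if (any(is_ver)) {
    k_obs <- kf[is_ver][1L]
    k_pred <- as.numeric(predict(arr, verification_C))
    verification <- list(temperature_C = verification_C, k_observed = k_obs,
                         k_predicted = k_pred,
                         pct_error = percent_error(k_obs, k_pred))
  }
  if (is.null(report_temperatures_C))
    report_temperatures_C <- sort(unique(temps))
  tab <- rate_table(arr, report_temperatures_C,
                    k_observed = kf[match(paste0("T", report_temperatures_C),
                                          names(series_list))])
  structure(list(first_order = fo, reversible = rv, arrhenius = arr,
                 verification = verification, table = tab),
            class = "hydrolysis_study_fit")
}

#' @export
print.hydrolysis_study_fit <- function(x, ...) {
  cat("Hydrolysis study fit\n\n")
  print(x$arrhenius)
  cat("\nRate / half-life table:\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$verification))
    cat(sprintf("\nVerification at %g degC: k_obs = %.3g, k_pred = %.3g, %%E = %.2f\n",
                x$verification$temperature_C, x$verification$k_observed,
                x$verification$k_predicted, x$verification$pct_error))
  invisible(x)
}

#' Quantify an unknown sample against a calibration curve
#'
#' Converts an instrument response to a concentration via
#' [invert_calibration()], optionally splitting total colistin into its
#' A and B forms.
#'
#' @param curve A `"calibration_curve"`.
#' @param response Instrument response(s).
#' @param split_cs Also return the colistin A/B partition of the result.
#' @param csa_fraction Mass fraction of colistin A for the split.
#' @return Concentration(s) in ug/mL; if `split_cs`, a data frame with
#'   columns `total`, `csa`, `csb`.
#' @export
quantify_sample <- function(curve, response, split_cs = FALSE,
                            csa_fraction = 0.301) {
  conc <- invert_calibration(curve, response)
  if (!split_cs) return(conc)
  sp <- vapply(conc, partition_cs, numeric(2), csa_fraction = csa_fraction)
  data.frame(total = conc, csa = sp["csa", ], csb = sp["csb", ])
}
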