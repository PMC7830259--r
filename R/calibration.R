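#' Fit a calibration curve (linear or quadratic)
#'
#' Least-squares polynomial fit of instrument response on concentration:
#' order 1 (colistin A and B) or order 2 (CMS, whose response is mildly
#' curved over the working range). Coefficient standard errors come from
#' the regression covariance.
#'
#' @param concentration Concentrations in ug/mL, all positive.
#' @param response Instrument responses (e.g. peak areas).
#' @param order Polynomial order, 1 or 2.
#' @param analyte Optional label ("CSA", "CSB", "CMS", ...).
#' @return Object of class `"calibration_curve"`: list with
#'   `coefficients` (intercept first), `se`, `r_squared`, `order`,
#'   `range` (concentration range), `analyte`, `n`, `sigma_resid`
#'   (residual standard deviation), and the `lm` fit.
#' @examples
#' x <- c(1.806, 2.408, 3.612, 4.816, 6.02, 6.622)
#' fit_calibration(x, 130.1 * x - 195.3, order = 1, analyte = "CSA")
#' @export
fit_calibration <- function(concentration, response, order = 1,
                            analyte = NA_character_) {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response), order %in% c(1, 2))
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (length(concentration) < order + 2)
    stop("need at least ", order + 2, " points for an order-", order, " fit",
         call. = FALSE)
  if (length(unique(concentration)) < order + 1)
    stop("design error: too few distinct concentration levels for order ",
         order, call. = FALSE)
  fit <- stats::lm(response ~ stats::poly(concentration, order, raw = TRUE))
  sm <- suppressWarnings(summary(fit))
  cf <- unname(stats::coef(fit))
  names(cf) <- c("intercept", "x", "x^2")[seq_len(order + 1)]
  se <- sm$coefficients[, 2L]; names(se) <- names(cf)
  structure(list(
    coefficients = cf, se = se, r_squared = sm$r.squared, order = order,
    range = range(concentration), analyte = analyte,
    n = length(concentration), sigma_resid = sm$sigma, lm = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  terms <- paste(sprintf("%.4g(+/-%.3g)%s", x$coefficients, x$se,
                         c("", "*x", "*x^2")[seq_along(x$coefficients)]),
                 collapse = " + ")
  cat(sprintf("Calibration curve%s (order %d, n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$order, x$n))
  cat("  y =", terms, "\n")
  cat(sprintf("  R^2 = %.4f  range %.4g-%.4g ug/mL\n",
              x$r_squared, x$range[1L], x$range[2L]))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) object$coefficients

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  cf <- object$coefficients
  drop(outer(concentration, seq_along(cf) - 1, `^`) %*% cf)
}

#' Invert a calibration curve: response to concentration
#'
#' Linear curves invert as (y - b)/a. Quadratic curves solve
#' a x^2 + b x + c = y and select the unique real root inside the
#' calibration concentration range; zero or two in-range roots raise an
#' inversion-ambiguity error (cannot occur for curves monotone on the
#' fitted range).
#'
#' @param curve A `"calibration_curve"`.
#' @param response Instrument response(s) to invert; must lie within the
#'   curve's fitted response range.
#' @return Concentration(s) in ug/mL.
#' @examples
#' x <- c(2, 6, 8, 12, 16, 20, 22)
#' cal <- fit_calibration(x, 130.1 * x - 195.3, order = 1)
#' invert_calibration(cal, 130.1 * 5 - 195.3)  # 5
#' @export
invert_calibration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  y_rng <- range(predict(curve, curve$range))
  tol <- 1e-8 * max(1, diff(y_rng))
  if (any(response < y_rng[1L] - tol | response > y_rng[2L] + tol))
    stop("response outside the curve's fitted response range ",
         sprintf("[%.4g, %.4g]", y_rng[1L], y_rng[2L]), call. = FALSE)
  cf <- curve$coefficients
  if (curve$order == 1L) return((response - cf[[1L]]) / cf[[2L]])
  vapply(response, function(y) {
    disc <- cf[[2L]]^2 - 4 * cf[[3L]] * (cf[[1L]] - y)
    if (disc < 0) stop("no real root when inverting the quadratic curve",
                       call. = FALSE)
    roots <- (-cf[[2L]] + c(-1, 1) * sqrt(disc)) / (2 * cf[[3L]])
    xtol <- 1e-7 * max(1, diff(curve$range))
    ok <- roots >= curve$range[1L] - xtol & roots <= curve$range[2L] + xtol
    if (sum(ok) != 1L)
      stop("inversion ambiguity: ", sum(ok), " roots inside the calibration range",
           call. = FALSE)
    roots[ok]
  }, numeric(1))
}

#' Extra sum-of-squares F test for pooling replicate calibration curves
#'
#' Compares independent per-run polynomial fits against a single global
#' fit with shared parameters:
#' \deqn{F = \frac{(SS_{pooled} - SS_{sep})/(df_{pooled} - df_{sep})}
#'            {SS_{sep}/df_{sep}}}
#' with p from the F distribution. A large p (> 0.05) supports pooling
#' the runs into one curve.
#'
#' @param curves A list of >= 2 data frames, each with columns
#'   `concentration` and `response` (designs may differ across runs).
#' @param order Polynomial order of the calibration model.
#' @return List with `F`, `p`, `pooled` (the global
#'   [fit_calibration()] curve), `pool_supported` (p > 0.05),
#'   `ss_pooled`, `ss_separate`, `df1`, `df2`.
#' @examples
#' x <- c(2, 6, 8, 12, 16, 20, 22)
#' run <- function(s) { set.seed(s); data.frame(concentration = x,
#'   response = 130.1 * x - 195.3 + rnorm(7, 0, 20)) }
#' pool_curves_f_test(lapply(1:3, run), order = 1)
#' @export
pool_curves_f_test <- function(curves, order = 1) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  p_par <- order + 1L
  sep <- lapply(curves, function(d) {
    stopifnot(all(c("concentration", "response") %in% names(d)))
    fit_calibration(d$concentration, d$response, order = order)
  })
  ss_sep <- sum(vapply(sep, function(f) sum(stats::resid(f$lm)^2), numeric(1)))
  df_sep <- sum(vapply(curves, nrow, integer(1))) - length(curves) * p_par
  all_d <- do.call(rbind, lapply(curves, function(d)
    d[, c("concentration", "response")]))
  pooled <- fit_calibration(all_d$concentration, all_d$response, order = order)
  ss_pooled <- sum(stats::resid(pooled$lm)^2)
  df_pooled <- nrow(all_d) - p_par
  df1 <- df_pooled - df_sep; df2 <- df_sep
  num <- max(ss_pooled - ss_sep, 0)  # nesting guarantees >= 0; clip roundoff
  Fstat <- if (num <= .Machine$double.eps * max(1, ss_pooled)) 0
           else if (ss_sep == 0) Inf
           else (num / df1) / (ss_sep / df2)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, p = pval, pooled = pooled, pool_supported = pval > 0.05,
       ss_pooled = ss_pooled, ss_separate = ss_sep, df1 = df1, df2 = df2)
}

#' Limits of detection and quantitation
#'
#' ICH-style limits from the response standard deviation and the
#' calibration slope: LOD = 3.3 sigma/S, LOQ = 10 sigma/S. The ratio
#' LOQ/LOD is the constant 10/3.3.
#'
#' @param sigma Standard deviation of the response, >= 0.
#' @param slope Calibration slope S (response per ug/mL), > 0.
#' @return Named numeric vector `c(LOD =, LOQ =)` in ug/mL.
#' @examples
#' lod_loq(1, 10)  # 0.33, 1.0
#' @export
lod_loq <- function(sigma, slope) {
  stopifnot(is.numeric(sigma), is.numeric(slope))
  if (any(sigma < 0)) stop("'sigma' must be >= 0", call. = FALSE)
  if (any(slope <= 0)) stop("'slope' must be > 0", call. = FALSE)
  c(LOD = 3.3 * sigma / slope, LOQ = 10 * sigma / slope)
}

#' Response standard deviation for LOD/LOQ
#'
#' Two conventions for the sigma entering [lod_loq()]: the standard
#' deviation of replicate responses at the lowest calibration level
#' (default), or the residual standard deviation of the fitted curve.
#'
#' @param concentration,response Calibration data (replicates included).
#' @param method `"lowest_level"` or `"residual"`.
#' @param curve A fitted `"calibration_curve"`, required for
#'   `method = "residual"`.
#' @return Scalar sigma in response units.
#' @export
calibration_sigma <- function(concentration, response,
                              method = c("lowest_level", "residual"),
                              curve = NULL) {
  method <- match.arg(method)
  if (method == "residual") {
    stopifnot(inherits(curve, "calibration_curve"))
    return(curve$sigma_resid)
  }
  low <- min(concentration)
  reps <- response[concentration == low]
  if (length(reps) < 2L)
    stop("lowest level has a single replicate: sigma undefined; ",
         "use method = 'residual'", call. = FALSE)
  stats::sd(reps)
}

#' Slope of the linear part of a quadratic calibration curve
#'
#' For analytes fitted with a quadratic curve (CMS), LOD/LOQ use the
#' slope of an OLS line over the lowest `n_levels` concentration levels,
#' where the response is effectively linear.
#'
#' @param concentration,response Calibration data.
#' @param n_levels Number of lowest distinct levels to use (default 3).
#' @return Scalar slope (response per ug/mL).
#' @export
linear_range_slope <- function(concentration, response, n_levels = 3) {
  lv <- sort(unique(concentration))
  if (length(lv) < n_levels)
    stop("fewer than ", n_levels, " distinct levels", call. = FALSE)
  keep <- concentration %in% lv[seq_len(n_levels)]
  unname(stats::coef(stats::lm(response[keep] ~ concentration[keep]))[2L])
}

#' Partition total colistin into its A and B forms
#'
#' The reference standard carries a fixed mass split between colistin A
#' and colistin B; the default CSA fraction is 0.301 (30.1%). The two
#' parts sum to the total exactly.
#'
#' @param total_cs Total colistin concentration, ug/mL, >= 0.
#' @param csa_fraction Mass fraction of colistin A, in (0, 1).
#' @return Named vector `c(csa =, csb =)` in ug/mL.
#' @examples
#' partition_cs(22)  # csa 6.622, csb 15.378
#' @export
partition_cs <- function(total_cs, csa_fraction = 0.301) {
  stopifnot(is.numeric(total_cs), is.numeric(csa_fraction))
  if (any(total_cs < 0)) stop("'total_cs' must be >= 0", call. = FALSE)
  if (csa_fraction <= 0 || csa_fraction >= 1)
    stop("'csa_fraction' must be inside (0, 1)", call. = FALSE)
  csa <- total_cs * csa_fraction
  c(csa = csa, csb = total_cs - csa)
}

#' Indirect colistimethate determination
#'
#' The circulating prodrug is obtained by difference:
#' CMS = CS(total, after hydrolysis) - CS(before hydrolysis). Valid only
#' when the hydrolysis step is (near-)complete; pass the hydrolysis
#' conditions to have the completeness checked against the kinetic
#' model, in which case an incomplete protocol triggers a warning and
#' the result carries attribute `incomplete_hydrolysis = TRUE`.
#'
#' @param cs_total Total CS after hydrolysis, ug/mL.
#' @param cs_before Circulating CS before hydrolysis, ug/mL;
#'   must not exceed `cs_total`.
#' @param hydrolysis Optional list with elements `params`
#'   (a [reversible_rates()] at the protocol temperature) and
#'   `duration_min`; completeness means <= `max_remaining_pct` percent
#'   of CMS left at the end of the protocol.
#' @param max_remaining_pct Completeness threshold, percent (default 10).
#' @return CMS concentration (as CS equivalents), ug/mL.
#' @examples
#' indirect_cms(10, 4)  # 6
#' @export
indirect_cms <- function(cs_total, cs_before, hydrolysis = NULL,
                         max_remaining_pct = 10) {
  stopifnot(is.numeric(cs_total), is.numeric(cs_before))
  if (any(cs_before < 0)) stop("'cs_before' must be >= 0", call. = FALSE)
  if (any(cs_total < cs_before))
    stop("cs_total < cs_before: negative CMS signals assay inconsistency",
         call. = FALSE)
  incomplete <- FALSE
  if (!is.null(hydrolysis)) {
    rem <- remaining_pct(100, hydrolysis$params, hydrolysis$duration_min)
    incomplete <- rem > max_remaining_pct
    if (incomplete)
      warning(sprintf(paste0("hydrolysis protocol leaves %.1f%% CMS unconverted ",
                             "(> %g%%): indirect CMS underestimated"),
                      rem, max_remaining_pct), call. = FALSE)
  }
  structure(cs_total - cs_before, incomplete_hydrolysis = incomplete)
}

#' Accuracy and precision summary of a validation table
#'
#' For a replicate table indexed by concentration level and analytical
#' run: accuracy per level-run as percent error of the run mean from
#' nominal, 100 |mean - nominal| / nominal; repeatability as the
#' within-run percent relative standard deviation; intermediate
#' precision as the percent RSD of run means across runs. Cells with a
#' single replicate report precision as missing, not zero.
#'
#' @param data Data frame with columns `level` (nominal concentration),
#'   `run` (run identifier) and `value` (measured concentration).
#' @return List of class `"validation_summary"`: `per_level` data frame
#'   with columns `level`, `accuracy_pct_error` (max over runs),
#'   `repeatability_pct_rsd` (max over runs), `intermediate_pct_rsd`;
#'   and `per_cell` with the level-by-run detail.
#' @export
accuracy_precision <- function(data) {
  stopifnot(is.data.frame(data), all(c("level", "run", "value") %in% names(data)))
  if (any(data$level == 0)) stop("nominal level 0: percent error undefined",
                                 call. = FALSE)
  cells <- do.call(rbind, lapply(split(data, data[c("level", "run")], drop = TRUE),
    function(d) {
      m <- mean(d$value)
      data.frame(level = d$level[1L], run = d$run[1L], n = nrow(d), mean = m,
                 pct_error = 100 * abs(m - d$level[1L]) / d$level[1L],
                 pct_rsd = if (nrow(d) >= 2L) 100 * stats::sd(d$value) / m
                           else NA_real_)
    }))
  rownames(cells) <- NULL
  per_level <- do.call(rbind, lapply(split(cells, cells$level), function(d) {
    run_means <- d$mean
    data.frame(level = d$level[1L],
               accuracy_pct_error = max(d$pct_error),
               repeatability_pct_rsd = if (all(is.na(d$pct_rsd))) NA_real_
                                       else max(d$pct_rsd, na.rm = TRUE),
               intermediate_pct_rsd = if (length(run_means) >= 2L)
                 100 * stats::sd(run_means) / mean(run_means) else NA_real_)
  }))
  rownames(per_level) <- NULL
  structure(list(per_level = per_level, per_cell = cells),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Validation summary (accuracy %Error, precision %RSD):\n")
  print(x$per_level, row.names = FALSE, digits = 4)
  invisible(x)
}
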