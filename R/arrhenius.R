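#' Universal gas constant (J mol^-1 K^-1)
#' @keywords internal
R_GAS <- 8.314

#' Fit the Arrhenius relationship across temperatures
#'
#' Ordinary least-squares regression of \eqn{\ln k} on \eqn{1/T}:
#' \deqn{\ln k = \ln A - E_a / (R T)}
#' with \eqn{R = 8.314} J mol\eqn{^{-1}} K\eqn{^{-1}}. The activation
#' energy is \eqn{E_a = -\mathrm{slope} \times R} and the pre-exponential
#' factor is the intercept \eqn{\ln A}.
#'
#' @param temperature_C Temperatures in degrees Celsius (or supply
#'   `temperature_K` directly).
#' @param k Rate constants in min^-1, all > 0, one per temperature.
#' @param temperature_K Optional temperatures in kelvin, overriding
#'   `temperature_C`.
#' @return Object of class `"arrhenius_fit"`: list with `Ea` (J/mol),
#'   `lnA` (ln min^-1), `r_squared`, `R_const`, `points` (data frame of
#'   temperature_K, k), `se` (Ea and lnA standard errors), and the
#'   underlying `lm` fit.
#' @examples
#' fit_arrhenius(c(40, 50, 60), c(0.0146, 0.0709, 0.4485))
#' @export
fit_arrhenius <- function(temperature_C = NULL, k, temperature_K = NULL) {
  if (is.null(temperature_K)) {
    stopifnot(!is.null(temperature_C))
    temperature_K <- vapply(temperature_C, function(x)
      temperature_point(x)$temperature_K, numeric(1))
  }
  stopifnot(is.numeric(k), length(k) == length(temperature_K))
  if (any(k <= 0)) stop("all rate constants must be > 0", call. = FALSE)
  if (length(unique(temperature_K)) < 2L)
    stop("need at least 2 distinct temperatures (rank-deficient design)",
         call. = FALSE)
  invT <- 1 / temperature_K
  fit <- stats::lm(log(k) ~ invT)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- if (length(k) == 2L) 1 else sm$r.squared
  se_slope <- if (length(k) > 2L) sm$coefficients[2L, 2L] else NA_real_
  se_int <- if (length(k) > 2L) sm$coefficients[1L, 2L] else NA_real_
  structure(list(
    Ea = -slope * R_GAS, lnA = unname(stats::coef(fit)[1L]),
    r_squared = r2, R_const = R_GAS,
    points = data.frame(temperature_K = temperature_K, k = k),
    se = c(Ea = R_GAS * se_slope, lnA = se_int), lm = fit
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius fit: ln k = lnA - Ea/(R T)\n")
  cat(sprintf("  Ea  = %.0f J mol^-1\n  lnA = %.3f (k in min^-1)\n  R^2 = %.4f  (n = %d temperatures)\n",
              x$Ea, x$lnA, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) c(Ea = object$Ea, lnA = object$lnA)

#' @export
summary.arrhenius_fit <- function(object, ...) {
  cat("Arrhenius regression of ln k on 1/T\n\n")
  print(cbind(Estimate = coef(object), `Std. Error` = object$se))
  cat(sprintf("\nR^2 = %.4f on %d temperatures; R = %.3f J mol^-1 K^-1\n",
              object$r_squared, nrow(object$points), object$R_const))
  invisible(object)
}

#' Predict a rate constant at a new temperature
#'
#' \eqn{k(T) = \exp(\ln A - E_a/(R T))}; strictly increasing in
#' temperature for positive activation energy. Extrapolation outside the
#' fitted range is permitted but flagged with an attribute (the
#' accelerated-stability design itself extrapolates 40-60 degC down
#' to 20 degC).
#'
#' @param object An `"arrhenius_fit"`.
#' @param temperature_C Temperature(s) in Celsius; or give `temperature_K`.
#' @param temperature_K Optional kelvin temperatures.
#' @param ... Unused.
#' @return Predicted k in min^-1 with attribute `extrapolated` (logical
#'   per temperature).
#' @examples
#' fit <- fit_arrhenius(c(40, 50, 60), c(0.0146, 0.0709, 0.4485))
#' predict(fit, 20)  # about 3e-4 min^-1
#' @export
predict.arrhenius_fit <- function(object, temperature_C = NULL,
                                  temperature_K = NULL, ...) {
  if (is.null(temperature_K)) {
    stopifnot(!is.null(temperature_C))
    temperature_K <- vapply(temperature_C, function(x)
      temperature_point(x)$temperature_K, numeric(1))
  }
  k <- exp(object$lnA - object$Ea / (object$R_const * temperature_K))
  rng <- range(object$points$temperature_K)
  structure(k, extrapolated = temperature_K < rng[1L] | temperature_K > rng[2L])
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  graphics::plot(1 / x$points$temperature_K, log(x$points$k),
                 xlab = "1/T (1/K)", ylab = "ln k", ...)
  graphics::abline(x$lnA, -x$Ea / x$R_const)
  invisible(x)
}

#' Relative verification error between observed and predicted rates
#'
#' Convention: \eqn{(k_{obs} - k_{pred})/k_{pred}}, reported as a
#' fraction. With the rounded 20 degC pair (0.0004 observed,
#' 0.0003 Arrhenius-predicted) this gives 0.33.
#'
#' @param k_observed Experimentally determined rate constant (> 0).
#' @param k_predicted Arrhenius-predicted rate constant (> 0).
#' @return Signed relative error as a fraction.
#' @examples
#' percent_error(0.0004, 0.0003)  # 0.333...
#' @export
percent_error <- function(k_observed, k_predicted) {
  stopifnot(is.numeric(k_observed), is.numeric(k_predicted))
  if (any(k_predicted <= 0) || any(k_observed <= 0))
    stop("rate constants must be > 0", call. = FALSE)
  (k_observed - k_predicted) / k_predicted
}

#' Time for the reversible scheme to reach a target percent remaining
#'
#' Inverts the closed-form trajectory:
#' \deqn{t = \frac{1}{k_f + k_r}\ln\frac{c_0 - A_{eq}}{\mathrm{target} - A_{eq}}.}
#' The target must lie strictly between the equilibrium plateau and c0;
#' below the plateau it is unreachable.
#'
#' @param params A [reversible_rates()] object.
#' @param target Target percent remaining.
#' @param c0 Initial percent (default 100).
#' @return Time in minutes.
#' @examples
#' time_to_remaining(reversible_rates(0.4485, 2.11e-3), 10)  # about 5.2 min
#' @export
time_to_remaining <- function(params, target, c0 = 100) {
  params <- as_reversible_rates(params)
  a_eq <- equilibrium_pct(c0, params)
  if (target >= c0) stop("'target' must be below the initial value", call. = FALSE)
  if (target <= a_eq)
    stop(sprintf("target %.3f%% is at or below the equilibrium plateau %.3f%%: unreachable",
                 target, a_eq), call. = FALSE)
  log((c0 - a_eq) / (target - a_eq)) / (params$k_forward + params$k_reverse)
}

#' Rate-constant and half-life table across temperatures
#'
#' Assembles the stability report: for each temperature the fitted or
#' Arrhenius-predicted rate constant and its half-life 0.693/k, flagging
#' temperatures outside the fitted range as extrapolated.
#'
#' @param fit An `"arrhenius_fit"`.
#' @param temperature_C Temperatures to tabulate, Celsius.
#' @param k_observed Optional named or positional vector of observed rate
#'   constants to report alongside the predictions (NA where absent).
#' @param use_ln2 Passed to [half_life()].
#' @return Data frame with columns `temperature_C`, `k_pred_per_min`,
#'   `k_obs_per_min`, `half_life_min`, `extrapolated`. Half-life uses the
#'   observed k where present, otherwise the predicted one.
#' @export
rate_table <- function(fit, temperature_C, k_observed = NULL, use_ln2 = FALSE) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  kp <- predict(fit, temperature_C)
  ko <- if (is.null(k_observed)) rep(NA_real_, length(temperature_C))
        else as.numeric(k_observed)
  kk <- ifelse(is.na(ko), as.numeric(kp), ko)
  data.frame(temperature_C = temperature_C,
             k_pred_per_min = as.numeric(kp),
             k_obs_per_min = ko,
             half_life_min = half_life(kk, use_ln2 = use_ln2),
             extrapolated = attr(kp, "extrapolated"))
}
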