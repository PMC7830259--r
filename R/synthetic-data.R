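default_reverse_rates <- c("40" = 2.2e-3, "50" = 3.54e-3, "60" = 2.11e-3)

default_calibration_truth <- list(
  CSA = c(intercept = -195.3, x = 130.1),
  CSB = c(intercept = -372.8, x = 125.2),
  CMS = c(intercept = 131.6, x = 20.97, `x^2` = 1.425))

#' Accelerated-hydrolysis study design
#'
#' Bundles everything the synthetic-data generator needs to emulate the
#' accelerated-stability study: the three accelerated temperatures plus
#' a room-temperature verification run, the 0-130 min sampling schedule
#' (2-min steps to 10 min, then 10-min steps), an Arrhenius ground truth
#' for the forward rate, per-temperature reverse rate constants, and a
#' multiplicative noise level.
#'
#' The default Arrhenius truth is the regression through the three
#' fitted accelerated rate constants (0.0146, 0.0709, 0.4485 min^-1 at
#' 40/50/60 degC), so forward rates generated from it reproduce those
#' constants to within the regression scatter. Reverse rates default to
#' the per-temperature fitted values (2.2e-3, 3.54e-3, 2.11e-3 min^-1);
#' temperatures without a fitted reverse rate (the verification run)
#' are generated as pure first-order decay (k_reverse = 0), matching
#' how the verification run was analysed.
#'
#' @param temperatures_C Accelerated temperatures, degC.
#' @param verification_C Verification temperature, degC (NA to omit).
#' @param schedule Sampling times in minutes for the accelerated runs.
#' @param verification_schedule Sampling times for the verification run,
#'   which is far slower: 10-min intervals out to 2400 min by default,
#'   spanning the room-temperature half-life (~38.5 h).
#' @param arrhenius_truth Named vector `c(Ea =, lnA =)` (J/mol, ln min^-1).
#' @param reverse_rates Named vector of k_reverse per accelerated
#'   temperature (names are temperatures in degC).
#' @param noise_cv Relative SD of the multiplicative Gaussian noise.
#' @param seed Integer seed; every generator call derives its stream
#'   deterministically from it.
#' @return List of class `"study_design"`.
#' @examples
#' study_design(seed = 1)
#' @export
study_design <- function(temperatures_C = c(40, 50, 60),
                         verification_C = 20,
                         schedule = sampling_schedule(130),
                         verification_schedule = seq(0, 2400, by = 10),
                         arrhenius_truth = NULL,
                         reverse_rates = default_reverse_rates,
                         noise_cv = 0.02,
                         seed = 1L) {
  stopifnot(length(unique(temperatures_C)) == length(temperatures_C),
            noise_cv >= 0)
  if (is.null(arrhenius_truth)) {
    fit <- fit_arrhenius(c(40, 50, 60), c(0.0146, 0.0709, 0.4485))
    arrhenius_truth <- c(Ea = fit$Ea, lnA = fit$lnA)
  }
  stopifnot(all(c("Ea", "lnA") %in% names(arrhenius_truth)))
  if (is.null(names(reverse_rates)))
    names(reverse_rates) <- as.character(temperatures_C)
  structure(list(temperatures_C = temperatures_C,
                 verification_C = verification_C,
                 schedule = schedule,
                 verification_schedule = verification_schedule,
                 arrhenius_truth = arrhenius_truth,
                 reverse_rates = reverse_rates,
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Accelerated-hydrolysis study design\n")
  cat("  temperatures:", paste0(x$temperatures_C, collapse = ", "),
      "degC; verification:", x$verification_C, "degC\n")
  cat(sprintf("  schedule: %d points, 0-%g min\n",
              length(x$schedule), max(x$schedule)))
  cat(sprintf("  truth: Ea = %.0f J/mol, lnA = %.3f; noise CV = %g; seed = %d\n",
              x$arrhenius_truth[["Ea"]], x$arrhenius_truth[["lnA"]],
              x$noise_cv, x$seed))
  invisible(x)
}

#' True rate parameters of a design at one temperature
#'
#' Forward rate from the design's Arrhenius truth,
#' k_f = exp(lnA - Ea/(R T)); reverse rate from the per-temperature
#' table (0, i.e. pure first-order decay, for temperatures absent from
#' the table such as the verification run).
#'
#' @param design A [study_design()].
#' @param temperature_C Temperature in degC.
#' @return A [reversible_rates()] object.
#' @export
design_rates <- function(design, temperature_C) {
  stopifnot(inherits(design, "study_design"))
  TK <- temperature_point(temperature_C)$temperature_K
  k_f <- exp(design$arrhenius_truth[["lnA"]] -
             design$arrhenius_truth[["Ea"]] / (R_GAS * TK))
  key <- as.character(temperature_C)
  k_r <- if (key %in% names(design$reverse_rates))
    design$reverse_rates[[key]] else 0
  reversible_rates(k_f, k_r)
}

# sub-seed per (seed, temperature): deterministic, distinct across temperatures
sub_seed <- function(seed, temperature_C) {
  (as.integer(seed) * 1009L + as.integer(round(temperature_C * 10))) %%
    2147483111L
}

#' Generate a percent-remaining decay series
#'
#' Values follow the closed-form reversible trajectory at the design's
#' true rates for that temperature, perturbed by multiplicative Gaussian
#' noise of CV `noise_cv`; the t = 0 point is pinned at exactly 100%
#' (normalisation to percent remaining). Negative noise draws are
#' truncated at 0 and flagged via attribute `truncated`.
#'
#' @param design A [study_design()].
#' @param temperature_C One of the design's temperatures (accelerated or
#'   verification).
#' @return A [conc_series()] on the percent scale; attribute `truth`
#'   carries the generating [reversible_rates()].
#' @examples
#' generate_decay_series(study_design(seed = 7), 60)
#' @export
generate_decay_series <- function(design, temperature_C) {
  stopifnot(inherits(design, "study_design"))
  if (!temperature_C %in% c(design$temperatures_C, design$verification_C))
    stop("temperature ", temperature_C, " degC is not part of the design",
         call. = FALSE)
  pars <- design_rates(design, temperature_C)
  tt <- if (!is.na(design$verification_C) &&
            temperature_C == design$verification_C)
    design$verification_schedule else design$schedule
  mu <- remaining_pct(100, pars, tt)
  set.seed(sub_seed(design$seed, temperature_C))
  v <- mu * (1 + stats::rnorm(length(tt), 0, design$noise_cv))
  truncated <- v < 0
  v[truncated] <- 0
  v[tt == 0] <- 100
  out <- conc_series(tt, v, unit = "percent", temperature_C = temperature_C)
  attr(out, "truth") <- pars
  attr(out, "truncated") <- any(truncated)
  out
}

#' Generate replicate calibration runs
#'
#' Responses are the truth polynomial evaluated at the levels plus
#' additive Gaussian noise, one independent draw per run; deterministic
#' under the seed.
#'
#' @param truth Named coefficient vector, intercept first (length 2
#'   linear, length 3 quadratic), or a `"calibration_curve"`.
#' @param levels Concentration levels, ug/mL.
#' @param n_runs Number of replicate runs.
#' @param noise_sd Additive response noise SD.
#' @param seed Integer seed.
#' @param analyte Label carried into the output.
#' @param range Optional valid concentration range; levels outside it
#'   raise a design warning.
#' @return Data frame with columns `analyte`, `run`, `concentration`,
#'   `response`.
#' @examples
#' generate_calibration_set(c(-195.3, 130.1), c(2, 6, 8, 12, 16, 20, 22),
#'                          n_runs = 3, noise_sd = 20, seed = 4)
#' @export
generate_calibration_set <- function(truth, levels, n_runs = 3,
                                     noise_sd = 20, seed = 1L,
                                     analyte = NA_character_, range = NULL) {
  if (inherits(truth, "calibration_curve")) {
    if (is.null(range)) range <- truth$range
    truth <- truth$coefficients
  }
  stopifnot(is.numeric(truth), length(truth) %in% c(2L, 3L),
            n_runs >= 1, noise_sd >= 0)
  if (!is.null(range) && any(levels < range[1L] | levels > range[2L]))
    warning("calibration level(s) outside the valid range ",
            sprintf("[%.4g, %.4g]", range[1L], range[2L]), call. = FALSE)
  mu <- drop(outer(levels, seq_along(truth) - 1, `^`) %*% truth)
  set.seed(as.integer(seed) %% 2147483111L)
  do.call(rbind, lapply(seq_len(n_runs), function(r)
    data.frame(analyte = analyte, run = r, concentration = levels,
               response = mu + stats::rnorm(length(levels), 0, noise_sd))))
}

#' Generate the complete synthetic study bundle
#'
#' One call produces everything the pipeline consumes: a percent-
#' remaining series per temperature (accelerated runs plus the
#' verification run), three-run calibration sets for CSA, CSB and CMS
#' at the printed level designs (CS levels derived from the CMS totals
#' via the 30.1% colistin-A mass fraction), and a truth manifest
#' recording every generating parameter for recovery tests.
#'
#' @param design A [study_design()].
#' @param dir Optional directory; when given, each series and
#'   calibration table is written as CSV and the truth manifest as JSON.
#' @param overwrite Refuse to write into an existing `dir` unless TRUE.
#' @param calibration_noise_sd Additive response noise SD for the
#'   calibration sets.
#' @return List of class `"study_bundle"`: `series` (named list of
#'   [conc_series()]), `calibration` (named list of data frames for
#'   CSA/CSB/CMS), `truth` (manifest list), `design`.
#' @examples
#' b <- generate_full_study(study_design(seed = 11))
#' names(b$series)
#' @export
generate_full_study <- function(design, dir = NULL, overwrite = FALSE,
                                calibration_noise_sd = 20) {
  stopifnot(inherits(design, "study_design"))
  temps <- c(design$temperatures_C,
             if (!is.na(design$verification_C)) design$verification_C)
  series <- lapply(temps, function(T) generate_decay_series(design, T))
  names(series) <- paste0("T", temps)

  cms_levels <- c(2, 6, 8, 12, 16, 20, 22)
  cs_totals <- c(6, 8, 12, 16, 20, 22)
  split <- vapply(cs_totals, partition_cs, numeric(2))
  levels <- list(CSA = split["csa", ], CSB = split["csb", ], CMS = cms_levels)
  calibration <- lapply(names(levels), function(a)
    generate_calibration_set(default_calibration_truth[[a]], levels[[a]],
                             n_runs = 3, noise_sd = calibration_noise_sd,
                             seed = sub_seed(design$seed, match(a, names(levels))),
                             analyte = a))
  names(calibration) <- names(levels)

  truth <- list(
    arrhenius = as.list(design$arrhenius_truth),
    rates = lapply(stats::setNames(temps, names(series)), function(T) {
      p <- design_rates(design, T)
      list(temperature_C = T, k_forward = p$k_forward, k_reverse = p$k_reverse)
    }),
    calibration = default_calibration_truth,
    noise_cv = design$noise_cv,
    calibration_noise_sd = calibration_noise_sd,
    csa_fraction = 0.301,
    seed = design$seed)

  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
      stop("output directory ", dir, " is not empty; set overwrite = TRUE",
           call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(series))
      write_series(series[[nm]], file.path(dir, paste0("series_", nm, ".csv")))
    for (nm in names(calibration))
      write_calibration(calibration[[nm]],
                        file.path(dir, paste0("calibration_", nm, ".csv")))
    write_truth_manifest(truth, file.path(dir, "truth.json"))
  }
  structure(list(series = series, calibration = calibration,
                 truth = truth, design = design),
            class = "study_bundle")
}
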